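# ---- categorical record tables ---------------------------------------------

#' Categorical data table with declared state domains
#'
#' A plain data.frame of state labels (all columns character) augmented with
#' the declared domain of every column and an optional designated class
#' column. Declared domains matter because a mutilated model must keep the
#' same state space as the gold standard even when some states drop out of
#' the records' support.
#'
#' @param df data.frame of state labels.
#' @param domains named list of state-label vectors, one per column; defaults
#'   to the sorted observed values.
#' @param class_var name of the class column, or `NULL`.
#' @param missing_token label that marks a missing cell (default `"?"`);
#'   never part of a domain.
#' @return an object of classes `bn_data` and `data.frame`.
#' @export
bn_data <- function(df, domains = NULL, class_var = NULL,
                    missing_token = "?") {
  df <- as.data.frame(lapply(df, as.character), stringsAsFactors = FALSE,
                      check.names = FALSE)
  if (is.null(domains)) {
    domains <- lapply(df, function(x) sort(unique(x[x != missing_token])))
  }
  if (!all(names(df) %in% names(domains))) {
    stop("every column needs a declared domain", call. = FALSE)
  }
  domains <- domains[names(df)]
  for (v in names(df)) {
    bad <- setdiff(unique(df[[v]]), c(domains[[v]], missing_token))
    if (length(bad)) {
      stop(sprintf("column '%s' has values outside its domain: %s", v,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(class_var) && !class_var %in% names(df)) {
    stop(sprintf("class column '%s' not in the table", class_var),
         call. = FALSE)
  }
  structure(df, domains = domains, class_var = class_var,
            missing_token = missing_token,
            class = c("bn_data", "data.frame"))
}

#' @export
print.bn_data <- function(x, ...) {
  cat(sprintf("<bn_data: %d records x %d variables%s>\n", nrow(x), ncol(x),
              if (!is.null(attr(x, "class_var")))
                paste0(", class = ", attr(x, "class_var")) else ""))
  NextMethod()
}

#' Domains of a data table
#' @param data a [bn_data()] table.
#' @return named list of state-label vectors.
#' @export
bn_domains <- function(data) attr(data, "domains")

#' Designated class column of a data table
#' @param data a [bn_data()] table.
#' @return column name or `NULL`.
#' @export
bn_class_var <- function(data) attr(data, "class_var")

#' Restrict a data table to a subset of columns
#' @param data a [bn_data()] table.
#' @param cols column names to keep.
#' @return a [bn_data()] over `cols`, domains and class designation carried.
#' @export
bn_restrict <- function(data, cols) {
  cv <- bn_class_var(data)
  bn_data(as.data.frame(data)[, cols, drop = FALSE],
          domains = bn_domains(data)[cols],
          class_var = if (!is.null(cv) && cv %in% cols) cv else NULL,
          missing_token = attr(data, "missing_token"))
}

#' Read a categorical CSV table
#'
#' Header row gives the variable names; all cells are state labels. Cells
#' equal to `missing_token` are kept verbatim and excluded from the inferred
#' domains.
#'
#' @param path CSV file path.
#' @param class_var designated class column, or `NULL`.
#' @param domains optional declared domains (inferred from the data
#'   otherwise).
#' @param missing_token missing-value token (default `"?"`).
#' @return a [bn_data()].
#' @export
read_bn_csv <- function(path, class_var = NULL, domains = NULL,
                        missing_token = "?") {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  bn_data(df, domains = domains, class_var = class_var,
          missing_token = missing_token)
}

#' Write a categorical table to CSV
#' @param data a [bn_data()].
#' @param path output path.
#' @export
write_bn_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# integer-coded view of the records: n x p matrix of 1-based domain codes
bn_codes <- function(data, vars = names(data)) {
  domains <- bn_domains(data)
  miss <- attr(data, "missing_token")
  codes <- vapply(vars, function(v) {
    x <- match(data[[v]], domains[[v]])
    if (anyNA(x)) {
      if (any(data[[v]] == miss)) {
        stop(sprintf("column '%s' contains missing values ('%s'); replace them before fitting",
                     v, miss), call. = FALSE)
      }
      stop(sprintf("column '%s' has a state outside its declared domain", v),
           call. = FALSE)
    }
    x
  }, integer(nrow(data)))
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = nrow(data))
  colnames(codes) <- vars
  codes
}

#' Equal-frequency discretization of a numeric column
#'
#' Utility for preparing mixed real/categorical tables: bins a numeric vector
#' into `k` classes at its empirical quantiles, labelling bins `bin1..bink`.
#'
#' @param x numeric vector.
#' @param k number of bins.
#' @return character vector of bin labels.
#' @export
discretize_equal_freq <- function(x, k = 3) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1),
                               na.rm = TRUE))
  cuts <- cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
  paste0("bin", cuts)
}
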