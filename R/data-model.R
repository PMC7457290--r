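# Core data structures: frequency tables, reconstructed count tables, and
# row-stochastic probability matrices, with validated CSV round trips.

#' Reconstruct integer transition counts from printed relative frequencies
#'
#' Published transition tables usually print row-wise relative frequencies at
#' two decimal places together with the number of observations `n` for the
#' row.  When `n` is small enough, the underlying integer counts are uniquely
#' determined: each count must be the integer nearest to `percent/100 * n`,
#' the counts must sum to `n`, and each reconstructed frequency must lie
#' within half a count of the printed one.  This function inverts the
#' rounding, and fails loudly when the printed row is inconsistent (which
#' signals a mis-transcribed table rather than a recoverable situation).
#'
#' @param percents Numeric vector of printed percentages for one source
#'   state, one entry per destination state; must sum to 100 within
#'   `0.05 * length(percents)` when `n > 0` (two-decimal printing allows up
#'   to half a unit in the last place per cell).
#' @param n Non-negative integer; observations from this source state.
#' @param label Optional row label used in error messages.
#' @return Integer vector of counts summing to `n` (all zeros when `n = 0`).
#' @examples
#' reconstruct_counts(c(3.31, 80.99, 0, 9.09, 5.79, 0.83, 0, 0), 121)
#' @export
reconstruct_counts <- function(percents, n, label = NULL) {
  who <- if (is.null(label)) "row" else paste0("row '", label, "'")
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n)) {
    stop(who, ": n must be a single non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (any(!is.finite(percents)) || any(percents < 0) || any(percents > 100)) {
    stop(who, ": percentages must lie in [0, 100]", call. = FALSE)
  }
  if (n == 0L) {
    if (any(percents != 0)) {
      stop(who, ": n = 0 but non-zero percentages printed", call. = FALSE)
    }
    return(integer(length(percents)))
  }
  tol_row <- 0.05 * length(percents)
  if (abs(sum(percents) - 100) > tol_row) {
    stop(who, ": percentages sum to ", format(sum(percents)),
         ", outside 100 +/- ", format(tol_row), call. = FALSE)
  }
  target <- percents / 100 * n
  x <- round(target)
  d <- sum(x) - n
  if (d != 0L) {
    # rounding ties (|target - x| exactly 0.5) are the only cells that can
    # legally absorb the discrepancy; shift those closest to the tie first
    resid <- target - x
    ord <- order(resid * sign(d))  # most room to move in the needed direction
    for (i in ord) {
      if (d == 0L) break
      shift <- -sign(d)
      if (abs(x[i] + shift - target[i]) <= 0.5 + 1e-9 && x[i] + shift >= 0) {
        x[i] <- x[i] + shift
        d <- d + shift
      }
    }
  }
  bad <- abs(x / n - percents / 100) > 0.5 / n + 1e-12
  if (sum(x) != n || any(bad)) {
    stop(who, ": printed percentages are inconsistent with n = ", n,
         " (offending cells: ",
         paste(which(if (sum(x) != n) rep(TRUE, length(x)) else bad),
               collapse = ", "), ")", call. = FALSE)
  }
  as.integer(x)
}

#' Read a transition relative-frequency table
#'
#' Expects a CSV with a `from` column of source-state labels, one percentage
#' column per destination state (header = destination label), and a trailing
#' `n` column of per-row observation counts.
#'
#' @param path Path to the CSV file.
#' @param arm Optional arm label attached to the result (defaults to the
#'   file name without extension).
#' @return An object of class `transition_frequencies`: a list with
#'   `labels` (state labels), `percents` (K x K matrix), `n` (integer
#'   vector) and `arm`.
#' @examples
#' read_frequency_table(bayestpm_fixture("table2_risperidone.csv"))
#' @export
read_frequency_table <- function(path, arm = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  if (nm[1L] != "from" || nm[length(nm)] != "n") {
    stop("frequency table must have a leading 'from' and a trailing 'n' ",
         "column; got columns: ", paste(nm, collapse = ", "), call. = FALSE)
  }
  labels <- nm[-c(1L, length(nm))]
  if (anyDuplicated(labels)) {
    stop("duplicated destination-state labels in header", call. = FALSE)
  }
  if (length(labels) < 2L) stop("need at least two states", call. = FALSE)
  if (!identical(as.character(df$from), labels)) {
    stop("source-state labels must match destination labels in order",
         call. = FALSE)
  }
  pc <- as.matrix(df[, labels, drop = FALSE])
  if (!is.numeric(pc) || anyNA(pc)) {
    stop("non-numeric percentage cell in ", path, call. = FALSE)
  }
  n <- df$n
  if (anyNA(n) || any(n < 0) || any(n != round(n))) {
    stop("'n' column must hold non-negative integers", call. = FALSE)
  }
  dimnames(pc) <- list(labels, labels)
  structure(
    list(labels = labels, percents = pc, n = as.integer(n),
         arm = arm %||% sub("\\.csv$", "", basename(path))),
    class = "transition_frequencies"
  )
}

#' Reconstruct a full count table from a frequency table
#'
#' Applies [reconstruct_counts()] row by row.
#'
#' @param freq A `transition_frequencies` object from
#'   [read_frequency_table()].
#' @return An object of class `transition_counts`: a list with `labels`,
#'   `counts` (K x K integer matrix), `n` (row totals) and `arm`.
#' @examples
#' freq <- read_frequency_table(bayestpm_fixture("table2_risperidone.csv"))
#' as_count_table(freq)
#' @export
as_count_table <- function(freq) {
  stopifnot(inherits(freq, "transition_frequencies"))
  K <- length(freq$labels)
  x <- matrix(0L, K, K, dimnames = list(freq$labels, freq$labels))
  for (i in seq_len(K)) {
    x[i, ] <- reconstruct_counts(freq$percents[i, ], freq$n[i],
                                 label = freq$labels[i])
  }
  count_table(x, arm = freq$arm)
}

#' Construct a transition count table
#'
#' @param counts K x K matrix of non-negative integer transition counts
#'   (rows = source states).
#' @param arm Optional arm label.
#' @param labels State labels; taken from `rownames(counts)` if present.
#' @return An object of class `transition_counts`.
#' @export
count_table <- function(counts, arm = NULL, labels = rownames(counts)) {
  counts <- as.matrix(counts)
  K <- nrow(counts)
  if (ncol(counts) != K || K < 2L) stop("counts must be square, K >= 2")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(labels)) labels <- as.character(seq_len(K))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(labels, labels)
  structure(list(labels = labels, counts = counts,
                 n = as.integer(rowSums(counts)), arm = arm),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Transition count table", if (!is.null(x$arm)) paste0(" (", x$arm, ")"),
      ": ", length(x$labels), " states, ", sum(x$n),
      " observed transitions\n", sep = "")
  print(cbind(x$counts, n = x$n))
  invisible(x)
}

#' Read a transition probability matrix from CSV
#'
#' Accepts either probabilities (rows summing to about 1) or percentages
#' (rows summing to about 100); the scale is detected from the row sums and
#' the returned matrix is always on the probability scale.
#'
#' @param path Path to a CSV with a `from` column and one column per
#'   destination state.
#' @return A row-stochastic numeric matrix with state labels as dimnames.
#' @examples
#' prior <- read_matrix(bayestpm_fixture("table1_expert_prior.csv"))
#' rowSums(prior)
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "from") stop("matrix CSV must start with a 'from' column")
  labels <- names(df)[-1L]
  if (anyDuplicated(labels)) stop("duplicated state labels in header")
  m <- as.matrix(df[, labels, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop("non-numeric cell in ", path)
  rs <- rowSums(m)
  if (all(abs(rs - 100) < 0.05 * ncol(m))) {
    m <- m / 100
  } else if (!all(abs(rs - 1) < 5e-4 * ncol(m))) {
    stop("rows sum to neither ~1 nor ~100; offending rows: ",
         paste(which(abs(rs - 1) >= 5e-4 * ncol(m) & abs(rs - 100) >= 0.05 * ncol(m)),
               collapse = ", "))
  }
  m <- m / rowSums(m)  # remove printed-rounding slack exactly
  dimnames(m) <- list(labels, labels)
  m
}

#' Write a probability matrix to CSV
#'
#' Probabilities are written at six decimal places, which round-trips through
#' [read_matrix()] to within 1e-6 per cell.
#'
#' @param m Row-stochastic matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  check_stochastic(m, what = "matrix to write")
  labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  df <- data.frame(from = labels, round(m, 6), check.names = FALSE)
  names(df) <- c("from", colnames(m) %||% labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: validate a row-stochastic matrix
check_stochastic <- function(m, tol = 1e-9, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (any(m < -tol) || any(m > 1 + tol)) {
    stop(what, " has entries outside [0, 1]", call. = FALSE)
  }
  bad <- abs(rowSums(m) - 1) > tol
  if (any(bad)) {
    stop(what, " rows do not sum to 1 (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
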