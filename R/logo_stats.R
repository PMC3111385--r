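# Per-column residue enrichment between a test set and a reference set of
# alignment rows, using a resampling statistic in the style of iceLogo.

#' Column-wise residue enrichment statistic
#'
#' For every requested column and residue, the frequency in the test rows is
#' compared to a null distribution obtained by repeatedly drawing
#' `nrow(test)` rows from the reference set with replacement.  The two-sided
#' empirical p-value is `(r + 1) / (iterations + 1)`, where `r` counts null
#' draws whose frequency deviates from the null mean at least as much as the
#' observed test frequency.  Gap symbols are excluded from all frequency
#' denominators.  No multiple-testing correction is applied by default.
#'
#' @param test character matrix of test rows (sequences x alignment columns).
#' @param reference character matrix of reference rows over the same columns.
#' @param columns alignment columns to evaluate (indices into the matrices).
#' @param iterations number of resampling draws.
#' @param alpha significance level used for the `significant` flag.
#' @param seed integer seed; results are a pure function of inputs and seed.
#' @return object of class `mip_icelogo`: list with `table` (data.frame:
#'   column, residue, freq_test, freq_ref, diff, p, significant), `alpha`,
#'   `iterations`, `seed`.
#' @export
icelogo <- function(test, reference, columns = seq_len(ncol(test)),
                    iterations = 1000L, alpha = 0.05, seed = 1L) {
  if (ncol(test) != ncol(reference))
    stop("input error: test and reference must have the same columns")
  if (any(columns < 1L | columns > ncol(test)))
    stop("input error: columns out of range")
  if (iterations < 1L) stop("input error: iterations must be >= 1")
  tt <- test[, columns, drop = FALSE]
  rr <- reference[, columns, drop = FALSE]
  nt <- nrow(tt)
  freqs <- function(m) {
    # residues x columns frequency matrix, gaps excluded per column
    vapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      x <- x[x != "-"]
      if (!length(x)) return(rep(NA_real_, length(.mip_aa)))
      tabulate(match(x, .mip_aa), length(.mip_aa)) / length(x)
    }, numeric(length(.mip_aa)))
  }
  f_test <- freqs(tt)
  f_ref <- freqs(rr)
  set.seed(seed)
  null_sum <- matrix(0, length(.mip_aa), ncol(tt))
  extreme <- matrix(0L, length(.mip_aa), ncol(tt))
  draws <- vector("list", iterations)
  for (b in seq_len(iterations)) {
    idx <- sample.int(nrow(rr), nt, replace = TRUE)
    draws[[b]] <- freqs(rr[idx, , drop = FALSE])
    null_sum <- null_sum + draws[[b]]
  }
  null_mean <- null_sum / iterations
  obs_dev <- abs(f_test - null_mean)
  for (b in seq_len(iterations))
    extreme <- extreme + (abs(draws[[b]] - null_mean) >= obs_dev - 1e-12)
  p <- (extreme + 1L) / (iterations + 1L)
  tab <- data.frame(
    column = rep(columns, each = length(.mip_aa)),
    residue = rep(.mip_aa, length(columns)),
    freq_test = as.vector(f_test),
    freq_ref = as.vector(f_ref),
    diff = as.vector(f_test - f_ref),
    p = as.vector(p),
    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$freq_test) & (tab$freq_test > 0 | tab$freq_ref > 0), ]
  tab$significant <- tab$p <= alpha
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha, iterations = iterations,
                 seed = seed), class = "mip_icelogo")
}

#' @export
print.mip_icelogo <- function(x, ...) {
  sig <- x$table[x$table$significant, ]
  cat("mip_icelogo:", length(unique(x$table$column)), "columns,",
      x$iterations, "iterations, alpha", x$alpha, "\n")
  cat("  significant residue/column pairs:", nrow(sig), "\n")
  invisible(x)
}

#' Render an enrichment logo as TSV and text (optionally a plot)
#'
#' Writes the full statistic table as TSV and a per-column text summary of
#' significantly enriched (`+`) and depleted (`-`) residues.  When ggplot2 is
#' installed and `plot_file` is given, a difference-bar plot is also written.
#'
#' @param x a `mip_icelogo`.
#' @param tsv_file output TSV path (NULL to skip).
#' @param text_file output text path (NULL returns the lines invisibly).
#' @param plot_file optional PDF path (requires ggplot2).
#' @return character vector of summary lines, invisibly.
#' @export
render_logo <- function(x, tsv_file = NULL, text_file = NULL,
                        plot_file = NULL) {
  if (!is.null(tsv_file))
    utils::write.table(x$table, tsv_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  sig <- x$table[x$table$significant, ]
  lines <- vapply(sort(unique(x$table$column)), function(cl) {
    s <- sig[sig$column == cl, ]
    up <- s$residue[s$diff > 0]
    dn <- s$residue[s$diff < 0]
    sprintf("col %4d  +[%s]  -[%s]", cl,
            paste(up, collapse = ""), paste(dn, collapse = ""))
  }, character(1))
  if (!is.null(text_file)) writeLines(lines, text_file)
  if (!is.null(plot_file)) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
      stop("dependency error: ggplot2 is required for plotting")
    d <- x$table
    p <- ggplot2::ggplot(d, ggplot2::aes(x = factor(column), y = diff,
                                         fill = significant)) +
      ggplot2::geom_col(position = "stack") +
      ggplot2::labs(x = "alignment column", y = "frequency difference")
    ggplot2::ggsave(plot_file, p, width = 10, height = 4)
  }
  invisible(lines)
}
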