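#' Exact paired binomial test of two per-subject outcome vectors
#'
#' Let `X_i`, `Y_i` be the 0/1 classification outcomes (correct/misclassified)
#' of the same subjects under two feature families. With `W` the number of
#' pairs with `X_i > Y_i` and `N` the number of discordant pairs
#' (`X_i != Y_i`), `W ~ Binomial(N, 1/2)` under the hypothesis of equal
#' performance. The one-sided p-value is the exact upper tail
#' `P(Bin(N, 1/2) >= W)`, computed from binomial coefficients; the two-sided
#' p-value is `min(1, 2 * min(upper tail, lower tail))`. `N = 0` (identical
#' outcomes) gives `p = 1` by convention.
#'
#' @param a,b `outcome_vector`s (from [loocv()]) or plain 0/1 vectors over
#'   the same subjects in the same order.
#' @param sidedness `"one"` (default) or `"two"`.
#' @return A `comparison_stat`: `W`, `N`, `p_value`, `sidedness`,
#'   `family_pair`.
#' @export
paired_binomial <- function(a, b, sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  lab <- c(outcome_label(a), outcome_label(b))
  a <- outcome_bits(a); b <- outcome_bits(b)
  if (length(a) != length(b))
    stopf("outcome vectors differ in length (%d vs %d)", length(a),
          length(b))
  ids_a <- names(a); ids_b <- names(b)
  if (!is.null(ids_a) && !is.null(ids_b) && !identical(ids_a, ids_b))
    stopf("outcome vectors cover different subjects (or a different order)")
  W <- sum(a == 1L & b == 0L)
  N <- sum(a != b)
  p <- binom_tail_upper(W, N)
  if (sidedness == "two")
    p <- min(1, 2 * min(p, binom_tail_lower(W, N)))
  structure(list(W = W, N = N, p_value = p, sidedness = sidedness,
                 family_pair = lab),
            class = "comparison_stat")
}

# Exact tails of Binomial(N, 1/2) from binomial coefficients.
binom_tail_upper <- function(W, N) {
  if (N == 0L) return(1)
  sum(choose(N, W:N)) / 2^N
}
binom_tail_lower <- function(W, N) {
  if (N == 0L) return(1)
  sum(choose(N, 0:W)) / 2^N
}

outcome_bits <- function(x) {
  if (inherits(x, "outcome_vector") ||
      (is.data.frame(x) && "correct" %in% names(x)))
    return(setNames(as.integer(x$correct), x$subject_id))
  x <- as.integer(x)
  if (any(!x %in% c(0L, 1L))) stopf("outcomes must be 0/1")
  x
}

outcome_label <- function(x) attr(x, "family_label") %||% NA_character_

#' @export
print.comparison_stat <- function(x, ...) {
  pair <- if (all(is.na(x$family_pair))) "" else
    sprintf(" [%s vs %s]", x$family_pair[1], x$family_pair[2])
  cat(sprintf("<comparison_stat>%s W = %d, N = %d, %s-sided p = %.4g\n",
              pair, x$W, x$N, x$sidedness, x$p_value))
  invisible(x)
}

#' Pairwise paired-binomial comparison of all feature families
#'
#' Every unordered pair of families is tested with [paired_binomial()],
#' oriented so that `W` counts wins of the family with the higher LOOCV
#' accuracy (ties keep the supplied order). All families must have been
#' classified on the identical subject set.
#'
#' @param outcomes named list of `outcome_vector`s, one per family.
#' @param sidedness passed to [paired_binomial()].
#' @return A `comparison_table` data.frame: `family_a` (higher accuracy),
#'   `family_b`, `accuracy_a`, `accuracy_b`, `W`, `N`, `p_value`,
#'   `sidedness`.
#' @export
compare_all_families <- function(outcomes, sidedness = "one") {
  fam <- names(outcomes)
  if (is.null(fam)) stopf("outcomes must be a named list")
  ids <- lapply(outcomes, function(o) o$subject_id)
  if (!all(vapply(ids, identical, TRUE, ids[[1]])))
    stopf("families were classified on different subject sets")
  rows <- list()
  for (i in seq_along(fam)) for (j in seq_along(fam)) {
    if (j <= i) next
    acc_i <- mean(outcomes[[i]]$correct)
    acc_j <- mean(outcomes[[j]]$correct)
    if (acc_j > acc_i) { a <- j; b <- i } else { a <- i; b <- j }
    st <- paired_binomial(outcomes[[a]], outcomes[[b]], sidedness)
    rows[[length(rows) + 1L]] <-
      data.frame(family_a = fam[a], family_b = fam[b],
                 accuracy_a = mean(outcomes[[a]]$correct),
                 accuracy_b = mean(outcomes[[b]]$correct),
                 W = st$W, N = st$N, p_value = st$p_value,
                 sidedness = st$sidedness, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Render a comparison table as Markdown
#'
#' Upper-triangular layout: one row/column per family, each filled cell
#' giving the p-value for that pair (the row family is the one `W` counts
#' wins for when it has the higher accuracy).
#'
#' @param tab a `comparison_table`.
#' @return Character vector of Markdown lines.
#' @export
format_comparison_markdown <- function(tab) {
  fams <- unique(c(tab$family_a, tab$family_b))
  cell <- function(f1, f2) {
    hit <- tab[(tab$family_a == f1 & tab$family_b == f2) |
                 (tab$family_a == f2 & tab$family_b == f1), ]
    if (!nrow(hit)) return("")
    sprintf("%.4f%s", hit$p_value[1],
            if (hit$p_value[1] < 0.05) "*" else "")
  }
  header <- paste0("| | ", paste(fams, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(fams) + 1L), collapse = "|"),
                "|")
  body <- vapply(seq_along(fams), function(i) {
    cells <- vapply(seq_along(fams), function(j)
      if (j <= i) if (j == i) "-" else "" else cell(fams[i], fams[j]),
      character(1))
    paste0("| ", fams[i], " | ", paste(cells, collapse = " | "), " |")
  }, character(1))
  c(header, sep, body)
}

#' Write an outcome CSV / comparison CSV
#'
#' @param outcomes an `outcome_vector`.
#' @param path file path.
#' @export
write_outcomes <- function(outcomes, path) {
  write.table(outcomes, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @param tab a `comparison_table`.
#' @export
write_comparison_table <- function(tab, path) {
  write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
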