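#' Chi-square goodness-of-fit test against a Mendelian ratio
#'
#' Tests observed class counts against arbitrary positive expected weights
#' (3:1, 15:1, 9:3:3:1, ...).  Uses the uncorrected Pearson statistic with
#' `classes - 1` degrees of freedom: no Yates continuity correction is
#' applied, matching standard practice for segregation tests.
#'
#' @param observed non-negative integer counts, length >= 2.
#' @param ratio positive class weights of the same length (default 3:1).
#' @return object of class `segregation_result`: observed, expected,
#'   chi2, df, p_value.
#' @examples
#' chi_square_ratio_test(c(448, 130))          # p = 0.16
#' chi_square_ratio_test(c(1038, 318))         # p = 0.19 (prints 0.188)
#' @export
chi_square_ratio_test <- function(observed, ratio = c(3, 1)) {
  if (any(observed < 0)) stop("negative counts are not allowed")
  if (length(observed) < 2L) stop("need at least 2 phenotype classes")
  if (length(ratio) != length(observed)) {
    stop("ratio and observed must have the same length")
  }
  if (any(ratio <= 0)) stop("expected ratio weights must be positive")
  total <- sum(observed)
  if (total <= 0) stop("total count must be positive")
  expected <- total * ratio / sum(ratio)
  if (any(expected == 0)) stop("zero expected count")
  ht <- suppressWarnings(stats::chisq.test(observed, p = ratio / sum(ratio)))
  structure(list(observed = observed, expected = expected,
                 chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("Segregation goodness-of-fit\n")
  cat("  observed:", paste(x$observed, collapse = " : "), "\n")
  cat("  expected:", paste(round(x$expected, 1), collapse = " : "), "\n")
  cat(sprintf("  chi2 = %.4f, df = %d, P = %.4f (%.2f)\n",
              x$chi2, x$df, x$p_value, round(x$p_value, 2)))
  invisible(x)
}

#' Infer an F2 genotype from an F3 progeny test
#'
#' A normal-phenotype F2 plant selfed to `n` F3 progeny is heterozygous if
#' any progeny is mutant, and called homozygous wild type if none is —
#' with misclassification probability (3/4)^n, the chance that a true
#' heterozygote shows zero mutant progeny.  An all-mutant family
#' contradicts the parent's normal phenotype and is flagged inconsistent.
#'
#' @param normal,mutant progeny counts.
#' @return list with `call` ("heterozygous", "homozygous_wt",
#'   "inconsistent" or "undetermined"), `n`, and `misclassification_prob`
#'   (only for homozygous calls, else NA).
#' @export
progeny_test_genotype <- function(normal, mutant) {
  stopifnot(normal >= 0, mutant >= 0)
  n <- as.integer(normal + mutant)
  if (n == 0L) {
    return(list(call = "undetermined", n = 0L,
                misclassification_prob = NA_real_))
  }
  if (mutant == 0L) {
    return(list(call = "homozygous_wt", n = n,
                misclassification_prob = (3 / 4)^n))
  }
  if (normal == 0L) {
    return(list(call = "inconsistent", n = n,
                misclassification_prob = NA_real_))
  }
  list(call = "heterozygous", n = n, misclassification_prob = NA_real_)
}

#' Batch progeny tests over a family table
#'
#' @param families data.frame with columns `normal` and `mutant` (one row
#'   per F3 family), plus optional identifiers carried through.
#' @return `families` with `call`, `n` and `misclassification_prob`
#'   columns appended.
#' @export
progeny_test_batch <- function(families) {
  stopifnot(all(c("normal", "mutant") %in% names(families)))
  res <- lapply(seq_len(nrow(families)), function(i) {
    progeny_test_genotype(families$normal[i], families$mutant[i])
  })
  families$call <- vapply(res, `[[`, character(1), "call")
  families$n <- vapply(res, `[[`, integer(1), "n")
  families$misclassification_prob <-
    vapply(res, `[[`, numeric(1), "misclassification_prob")
  families
}
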