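check_ct_table <- function(ct_table) {
  need <- c("sample", "condition", "gene", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss) > 0L) {
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  invisible(ct_table)
}

# collapse technical replicates by arithmetic mean of Ct
collapse_tech <- function(ct_table) {
  stats::aggregate(ct ~ sample + condition + gene + bio_rep,
                   data = ct_table, FUN = mean)
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged within each biological replicate;
#' dCt = Ct(target) - Ct(reference) per biological replicate;
#' ddCt = mean dCt of a condition minus the mean dCt of the calibrator
#' condition; fold change = `2^-ddCt`.  Amplification efficiency is fixed
#' at 100% (the base 2); biological replicates are the unit of inference.
#'
#' @param ct_table data.frame with columns sample, condition, gene,
#'   bio_rep, tech_rep, ct.
#' @param target target gene name.
#' @param reference internal reference gene (present in every
#'   condition/bio_rep).
#' @param calibrator condition whose mean fold change is 1 by
#'   construction.
#' @return object of class `rel_expression`: `summary` (condition, fold,
#'   dct_mean, dct_sd, n_bio) and `per_rep` (condition, bio_rep, dct,
#'   ddct, fold).
#' @export
ddct <- function(ct_table, target, reference, calibrator) {
  check_ct_table(ct_table)
  ct_table <- ct_table[ct_table$gene %in% c(target, reference), ,
                       drop = FALSE]
  if (!calibrator %in% ct_table$condition) {
    stop("calibrator condition '", calibrator, "' not in table")
  }
  m <- collapse_tech(ct_table)
  tg <- m[m$gene == target, ]
  rf <- m[m$gene == reference, ]
  key <- function(d) paste(d$sample, d$condition, d$bio_rep, sep = "\r")
  idx <- match(key(tg), key(rf))
  if (anyNA(idx)) {
    stop("missing reference-gene measurements for: ",
         paste(unique(paste(tg$condition, "bio_rep", tg$bio_rep)[is.na(idx)]),
               collapse = "; "))
  }
  per <- data.frame(condition = tg$condition, bio_rep = tg$bio_rep,
                    dct = tg$ct - rf$ct[idx], stringsAsFactors = FALSE)
  cal_mean <- mean(per$dct[per$condition == calibrator])
  per$ddct <- per$dct - cal_mean
  per$fold <- 2^(-per$ddct)
  summ <- do.call(rbind, lapply(split(per, per$condition), function(d) {
    data.frame(condition = d$condition[1L],
               fold = 2^(-(mean(d$dct) - cal_mean)),
               dct_mean = mean(d$dct),
               dct_sd = stats::sd(d$dct),
               n_bio = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, per_rep = per, target = target,
                 reference = reference, calibrator = calibrator),
            class = "rel_expression")
}

#' @export
print.rel_expression <- function(x, ...) {
  cat(sprintf("2^-ddCt relative expression of %s (ref %s, calibrator %s)\n",
              x$target, x$reference, x$calibrator))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Compare expression between two conditions
#'
#' Two-sided Welch t-test on per-biological-replicate dCt values (tested
#' on the Ct scale, where noise is approximately normal, rather than on
#' fold changes).
#'
#' @param rel a [ddct()] result.
#' @param cond_a,cond_b condition names.
#' @param alpha significance level (default 0.01).
#' @return list: p_value, significant, alpha, fold_ratio (a vs b).
#' @export
compare_conditions <- function(rel, cond_a, cond_b, alpha = 0.01) {
  stopifnot(inherits(rel, "rel_expression"))
  a <- rel$per_rep$dct[rel$per_rep$condition == cond_a]
  b <- rel$per_rep$dct[rel$per_rep$condition == cond_b]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 biological replicates per condition")
  }
  p <- if (isTRUE(all.equal(stats::var(c(a - mean(a), b - mean(b))), 0))) {
    if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  } else {
    stats::t.test(a, b)$p.value
  }
  list(p_value = p, significant = p < alpha, alpha = alpha,
       fold_ratio = 2^(-(mean(a) - mean(b))))
}

#' Feedback-regulation report across organs
#'
#' For each organ, contrasts treatment against mock within each genotype
#' (wild type and mutant) via [ddct()] and [compare_conditions()], and
#' classifies the response as "repressed", "induced" or "unchanged"
#' (significance flag plus fold direction).  Organs missing a treatment
#' arm are reported with status "incomplete".
#'
#' @param ct_table Ct table whose `sample` column holds the organ and
#'   whose `condition` column combines genotype and treatment as
#'   "genotype:treatment" (e.g. "WT:BL", "mutant:mock").
#' @param target,reference gene names.
#' @param genotypes character vector of genotype labels (default
#'   c("WT", "mutant")).
#' @param treatment,mock treatment labels (defaults "BL", "mock").
#' @param alpha significance level (default 0.01).
#' @return data.frame(organ, genotype, fold, p_value, status).
#' @export
feedback_report <- function(ct_table, target, reference,
                            genotypes = c("WT", "mutant"),
                            treatment = "BL", mock = "mock",
                            alpha = 0.01) {
  check_ct_table(ct_table)
  rows <- list()
  for (organ in unique(ct_table$sample)) {
    sub <- ct_table[ct_table$sample == organ, , drop = FALSE]
    for (g in genotypes) {
      cond_trt <- paste(g, treatment, sep = ":")
      cond_mock <- paste(g, mock, sep = ":")
      have <- unique(sub$condition)
      if (!all(c(cond_trt, cond_mock) %in% have)) {
        rows[[length(rows) + 1L]] <- data.frame(
          organ = organ, genotype = g, fold = NA_real_,
          p_value = NA_real_, status = "incomplete",
          stringsAsFactors = FALSE)
        next
      }
      rel <- ddct(sub[sub$condition %in% c(cond_trt, cond_mock), ],
                  target, reference, calibrator = cond_mock)
      cmp <- compare_conditions(rel, cond_trt, cond_mock, alpha = alpha)
      fold <- rel$summary$fold[rel$summary$condition == cond_trt]
      status <- if (!cmp$significant) "unchanged" else
        if (fold < 1) "repressed" else "induced"
      rows[[length(rows) + 1L]] <- data.frame(
        organ = organ, genotype = g, fold = fold,
        p_value = cmp$p_value, status = status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
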