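#' Per-site SNP index
#'
#' The fraction of reads carrying the mutant (alt) allele:
#' `alt_depth / (ref_depth + alt_depth)`.  Undefined (NA, with a notice)
#' at zero total depth.
#'
#' @param ref_depth,alt_depth non-negative read counts (vectorized).
#' @return numeric vector in \[0, 1\] (NA where depth is zero).
#' @export
compute_snp_index <- function(ref_depth, alt_depth) {
  stopifnot(all(ref_depth >= 0), all(alt_depth >= 0))
  total <- ref_depth + alt_depth
  out <- ifelse(total > 0, alt_depth / total, NA_real_)
  if (anyNA(out)) {
    message(sum(is.na(out)),
            " site(s) with zero depth: SNP index undefined, excluded")
  }
  out
}

wt_state_call <- function(ref_depth, alt_depth, hom_threshold = 0.9) {
  total <- ref_depth + alt_depth
  frac <- ifelse(total > 0, alt_depth / total, NA_real_)
  ifelse(is.na(frac), "missing",
         ifelse(frac >= hom_threshold, "alt",
                ifelse(frac <= 1 - hom_threshold, "ref", "het")))
}

#' Derive mutant-specific SNP sites from two variant tables
#'
#' The modified-MutMap contrast: both the mutant bulk and the wild-type
#' parent are called against the same public reference, and only sites
#' where the bulk carries the alternate allele while the parent is
#' reference-homozygous are retained.  Sites where the parent shares the
#' alternate allele (or is heterozygous, or has no coverage) are parental
#' background rather than induced mutations and are removed.
#'
#' @param mutant_table,wt_table data.frames with chrom, pos, ref, alt,
#'   ref_depth, alt_depth (an optional "reference" attribute names the
#'   reference build and is checked for equality).
#' @return the retained sites, sorted by (chrom, pos), with `snp_index`
#'   and `wt_state` columns.
#' @export
derive_mutant_specific_sites <- function(mutant_table, wt_table) {
  ref_m <- attr(mutant_table, "reference")
  ref_w <- attr(wt_table, "reference")
  if (!is.null(ref_m) && !is.null(ref_w) && !identical(ref_m, ref_w)) {
    stop("variant tables were called against different references: '",
         ref_m, "' vs '", ref_w, "'")
  }
  if (length(intersect(unique(mutant_table$chrom),
                       unique(wt_table$chrom))) == 0L) {
    stop("no shared chromosome names between the two tables; ",
         "are they on the same reference build?")
  }
  for (nm in c("mutant", "wt")) {
    tab <- if (nm == "mutant") mutant_table else wt_table
    if (anyDuplicated(site_key(tab$chrom, tab$pos))) {
      stop("duplicate positions in the ", nm, " table")
    }
  }
  keys_w <- site_key(wt_table$chrom, wt_table$pos)
  wt_state_all <- wt_state_call(wt_table$ref_depth, wt_table$alt_depth)
  idx <- match(site_key(mutant_table$chrom, mutant_table$pos), keys_w)
  wt_state <- ifelse(is.na(idx), "missing", wt_state_all[idx])
  out <- mutant_table
  out$wt_state <- wt_state
  out$snp_index <- compute_snp_index(out$ref_depth, out$alt_depth)
  out <- out[out$alt_depth > 0L & out$wt_state == "ref" &
               !is.na(out$snp_index), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Sliding-window mean of SNP indices
#'
#' Averages SNP indices over a moving window of `k` consecutive SNPs,
#' shifting the window one SNP at a time and never spanning chromosomes.
#' The x-coordinate of each window is the midpoint between its first and
#' last member SNP.
#'
#' @param sites variant table with chrom, pos, snp_index (sorted within
#'   chromosome; resorted defensively).
#' @param k window size in SNPs (default 5).
#' @return data.frame(chrom, x, mean_index, start_pos, end_pos, n) with
#'   one row per window; chromosomes with fewer than `k` SNPs contribute
#'   no windows.
#' @export
sliding_window <- function(sites, k = 5L) {
  stopifnot(k >= 1L)
  sites <- sites[order(sites$chrom, sites$pos), ]
  out <- lapply(split(sites, sites$chrom), function(s) {
    n <- nrow(s)
    if (n < k) return(NULL)
    i <- seq_len(n - k + 1L)
    cs <- cumsum(c(0, s$snp_index))
    data.frame(chrom = s$chrom[1L],
               x = (s$pos[i] + s$pos[i + k - 1L]) / 2,
               mean_index = (cs[i + k] - cs[i]) / k,
               start_pos = s$pos[i],
               end_pos = s$pos[i + k - 1L],
               n = k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), x = numeric(0),
                      mean_index = numeric(0), start_pos = integer(0),
                      end_pos = integer(0), n = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Call candidate regions from windowed SNP indices
#'
#' Maximal runs of consecutive windows whose mean index is at or above the
#' threshold become candidate regions; region bounds are the first and
#' last member SNP positions of the run.  Regions are ranked by peak mean
#' index, then by length, with ties broken by chromosome name and start.
#'
#' @param windows output of [sliding_window()].
#' @param threshold mean-index threshold (default 0.9).
#' @return data.frame(chrom, start, end, peak_index, n_windows, n_sites),
#'   best region first; zero rows (with a warning) if nothing passes.
#' @export
call_candidate_region <- function(windows, threshold = 0.9) {
  regions <- lapply(split(windows, windows$chrom), function(w) {
    w <- w[order(w$start_pos), ]
    pass <- w$mean_index >= threshold
    if (!any(pass)) return(NULL)
    runs <- rle(pass)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    do.call(rbind, lapply(keep, function(j) {
      i0 <- starts[j]; i1 <- ends[j]
      k <- w$n[1L]
      data.frame(chrom = w$chrom[1L],
                 start = w$start_pos[i0],
                 end = w$end_pos[i1],
                 peak_index = max(w$mean_index[i0:i1]),
                 n_windows = i1 - i0 + 1L,
                 n_sites = (i1 - i0) + k,
                 stringsAsFactors = FALSE)
    }))
  })
  regions <- do.call(rbind, regions)
  if (is.null(regions) || nrow(regions) == 0L) {
    warning("no window reaches mean SNP index >= ", threshold)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), peak_index = numeric(0),
                      n_windows = integer(0), n_sites = integer(0)))
  }
  ord <- order(-regions$peak_index, -(regions$end - regions$start),
               regions$chrom, regions$start)
  regions <- regions[ord, ]
  rownames(regions) <- NULL
  regions
}

#' Plot windowed SNP indices per chromosome
#'
#' @param windows output of [sliding_window()].
#' @param regions optional candidate regions to shade.
#' @param threshold horizontal guide line.
#' @export
plot_snp_index <- function(windows, regions = NULL, threshold = 0.9) {
  chroms <- unique(windows$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(2, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    w <- windows[windows$chrom == ch, ]
    plot(w$x / 1e3, w$mean_index, type = "l", ylim = c(0, 1),
         xlab = "", ylab = "SNP index", main = ch, col = "grey30")
    graphics::abline(h = threshold, lty = 2, col = "red")
    if (!is.null(regions)) {
      r <- regions[regions$chrom == ch, ]
      if (nrow(r) > 0L) {
        graphics::rect(r$start / 1e3, 0, r$end / 1e3, 1,
                       col = grDevices::adjustcolor("red", 0.15),
                       border = NA)
      }
    }
  }
  invisible(NULL)
}
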