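#' Kosambi mapping function
#'
#' Converts a recombination fraction to map distance,
#' `d = 25 ln((1 + 2r) / (1 - 2r))` cM, which accounts for crossover
#' interference.  [kosambi_r()] is the exact inverse,
#' `r = tanh(d / 50) / 2`.
#'
#' @param r recombination fraction(s) in \[0, 0.5).
#' @return map distance(s) in cM.
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("Kosambi distance is defined for 0 <= r < 0.5")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @param d map distance(s) in cM (>= 0).
#' @export
kosambi_r <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  tanh(d / 50) / 2
}

#' Recombination fraction between a marker and a recessive trait locus
#'
#' Among mutant-class F2 plants (homozygous recessive at the trait locus)
#' each of the 2n marker alleles is, independently, a recombinant with
#' probability r.  With `k` recombinant alleles observed the maximum
#' likelihood estimate is `r_hat = k / (2n)` (capped at 0.5) and the LOD
#' score is the base-10 likelihood ratio against independence (r = 0.5).
#' Genotype codes: A = wild-parent homozygote, H = heterozygote,
#' B = mutant-parent homozygote; missing codes (NA or "-") are dropped.
#'
#' @param genotypes character vector of marker genotypes of the
#'   mutant-class plants.
#' @return list of class `linkage_estimate`: r_hat, lod, cm, n, k.
#' @export
estimate_r_trait <- function(genotypes) {
  g <- genotypes[!is.na(genotypes) & genotypes != "-"]
  if (length(g) == 0L) stop("no mutant-class individuals with genotypes")
  bad <- setdiff(unique(g), c("A", "H", "B"))
  if (length(bad) > 0L) {
    stop("invalid genotype code(s): ", paste(bad, collapse = ", "))
  }
  n <- length(g)
  k <- sum(g == "A") * 2L + sum(g == "H")   # recombinant marker alleles
  m <- 2L * n
  r_hat <- min(k / m, 0.5)
  loglik <- function(r) {
    if (r <= 0) {
      if (k == 0L) return(0)
      return(-Inf)
    }
    k * log10(r) + (m - k) * log10(1 - r)
  }
  lod <- max(loglik(r_hat) - loglik(0.5), 0)
  structure(list(r_hat = r_hat, lod = lod,
                 cm = if (r_hat < 0.5) kosambi_cm(r_hat) else Inf,
                 n = n, k = k),
            class = "linkage_estimate")
}

#' @export
print.linkage_estimate <- function(x, ...) {
  cat(sprintf("r_hat = %.4f (%d/%d alleles), LOD = %.2f, %.2f cM\n",
              x$r_hat, x$k, 2L * x$n, x$lod,
              if (is.finite(x$cm)) x$cm else NA_real_))
  invisible(x)
}

# Joint F2 genotype-class probabilities and expected recombinant-gamete
# counts for a pair of codominant loci in coupling; built by enumerating
# the 4 x 4 gamete pairs.  Genotypes are coded as copies of the
# mutant-parent allele (0/1/2) at each locus.
f2_pair_model <- function(r) {
  hap <- expand.grid(a = 0:1, b = 0:1)        # 1 = mutant-parent allele
  hap$p <- ifelse(hap$a == hap$b, (1 - r) / 2, r / 2)
  hap$rec <- as.integer(hap$a != hap$b)
  prob <- matrix(0, 3, 3)
  rec <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    ga <- hap$a[i] + hap$a[j] + 1L
    gb <- hap$b[i] + hap$b[j] + 1L
    pij <- hap$p[i] * hap$p[j]
    prob[ga, gb] <- prob[ga, gb] + pij
    rec[ga, gb] <- rec[ga, gb] + pij * (hap$rec[i] + hap$rec[j])
  }
  list(prob = prob, exp_rec = ifelse(prob > 0, rec / prob, 0))
}

#' Recombination fraction between two codominant markers in an F2
#'
#' Maximum likelihood via EM over the phase-ambiguous double-heterozygote
#' class; LOD against r = 0.5 from the multinomial likelihood.
#'
#' @param g1,g2 genotype code vectors (A/H/B, missing dropped pairwise).
#' @param max_iter,tol EM controls.
#' @return a `linkage_estimate`.
#' @export
estimate_r_markers <- function(g1, g2, max_iter = 100L, tol = 1e-10) {
  keep <- !is.na(g1) & !is.na(g2) & g1 != "-" & g2 != "-"
  g1 <- g1[keep]; g2 <- g2[keep]
  if (length(g1) == 0L) stop("no individuals scored at both markers")
  code <- c(A = 1L, H = 2L, B = 3L)
  if (!all(g1 %in% names(code)) || !all(g2 %in% names(code))) {
    stop("invalid genotype codes")
  }
  counts <- matrix(0, 3, 3)
  for (i in seq_along(g1)) {
    counts[code[[g1[i]]], code[[g2[i]]]] <-
      counts[code[[g1[i]]], code[[g2[i]]]] + 1
  }
  n <- sum(counts)
  r <- 0.25
  for (it in seq_len(max_iter)) {
    mod <- f2_pair_model(r)
    exp_rec_total <- sum(counts * mod$exp_rec)
    r_new <- min(max(exp_rec_total / (2 * n), 1e-9), 0.5)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  ll <- function(rr) {
    p <- f2_pair_model(rr)$prob
    sum(counts[counts > 0] * log10(p[counts > 0]))
  }
  lod <- max(ll(r) - ll(0.5), 0)
  r_hat <- min(r, 0.5)
  structure(list(r_hat = r_hat, lod = lod,
                 cm = if (r_hat < 0.5) kosambi_cm(r_hat) else Inf,
                 n = n, k = NA_integer_),
            class = "linkage_estimate")
}

#' BSA pre-screen of markers against phenotype bulks
#'
#' Emulates bulked-segregant marker screening: DNA of a few mutant plants
#' and a few wild-type plants is pooled, and a marker passes when the
#' mutant bulk is fixed for one parental allele while the wild-type bulk
#' shows a different allele content (mixed or opposite).
#'
#' @param marker_table a marker genotype table from
#'   [simulate_marker_table()] (data.frame, one row per individual,
#'   genotype columns coded A/H/B plus a `phenotype` column).
#' @param wt_bulk,mutant_bulk row indices (or individual ids) of the bulk
#'   members.
#' @param markers marker column names (default: all genotype columns).
#' @return data.frame(marker, scp_alleles, wt_alleles, pass).
#' @export
bsa_screen <- function(marker_table, wt_bulk, mutant_bulk,
                       markers = NULL) {
  ids <- if ("id" %in% names(marker_table)) marker_table$id else
    seq_len(nrow(marker_table))
  resolve <- function(members) {
    i <- match(members, ids)
    if (anyNA(i)) {
      stop("bulk member(s) not in table: ",
           paste(members[is.na(i)], collapse = ", "))
    }
    i
  }
  wt_i <- resolve(wt_bulk)
  mu_i <- resolve(mutant_bulk)
  if (is.null(markers)) {
    markers <- setdiff(names(marker_table), c("id", "phenotype"))
  }
  allele_content <- function(codes) {
    codes <- codes[!is.na(codes) & codes != "-"]
    sort(unique(unlist(list(A = "A", H = c("A", "B"), B = "B")[codes])))
  }
  rows <- lapply(markers, function(m) {
    scp <- allele_content(marker_table[[m]][mu_i])
    wt <- allele_content(marker_table[[m]][wt_i])
    pass <- length(scp) == 1L && !setequal(scp, wt)
    data.frame(marker = m,
               scp_alleles = paste(scp, collapse = "/"),
               wt_alleles = paste(wt, collapse = "/"),
               pass = pass, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- linkage-group construction -------------------------------------------

union_find_groups <- function(items, edges) {
  parent <- stats::setNames(items, items)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges$a[i]); rb <- find(edges$b[i])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(items, find, character(1))
  split(items, roots)
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

order_markers <- function(markers, dmat, exhaustive_max = 8L) {
  m <- length(markers)
  if (m <= 2L) return(markers)
  path_len <- function(ord) {
    sum(dmat[cbind(ord[-m], ord[-1L])])
  }
  if (m <= exhaustive_max) {
    perms <- permutations(m)
    # fix orientation: first index < last index halves the search
    perms <- perms[perms[, 1L] < perms[, m], , drop = FALSE]
    best <- perms[which.min(apply(perms, 1L, path_len)), ]
  } else {
    # greedy seriation: start from the most eccentric marker, append the
    # nearest unplaced marker
    start <- which.max(apply(dmat, 1L, max))
    best <- start
    left <- setdiff(seq_len(m), start)
    while (length(left) > 0L) {
      nxt <- left[which.min(dmat[best[length(best)], left])]
      best <- c(best, nxt)
      left <- setdiff(left, nxt)
    }
  }
  markers[best]
}

#' Group and order markers by pairwise linkage
#'
#' Single-linkage clustering on the graph of marker pairs with LOD at or
#' above the threshold, then within-group ordering that minimizes the sum
#' of adjacent map distances (exhaustive search up to 8 markers, greedy
#' seriation above).  Group membership is invariant to marker input order;
#' the orientation of each ordered group is arbitrary.
#'
#' @param estimates data.frame with columns `a`, `b` (marker names),
#'   `r_hat`, `lod` — e.g. built with [pairwise_linkage()].
#' @param lod_threshold minimum LOD to link two markers (default 4).
#' @return list of groups; each a data.frame(marker, cm) with cumulative
#'   Kosambi positions along the ordered group.
#' @export
group_markers <- function(estimates, lod_threshold = 4) {
  markers <- sort(unique(c(estimates$a, estimates$b)))
  linked <- estimates[estimates$lod >= lod_threshold, , drop = FALSE]
  groups <- union_find_groups(markers,
                              data.frame(a = linked$a, b = linked$b))
  dmat <- matrix(Inf, length(markers), length(markers),
                 dimnames = list(markers, markers))
  diag(dmat) <- 0
  for (i in seq_len(nrow(estimates))) {
    d <- if (estimates$r_hat[i] < 0.5) kosambi_cm(estimates$r_hat[i])
         else Inf
    dmat[estimates$a[i], estimates$b[i]] <- d
    dmat[estimates$b[i], estimates$a[i]] <- d
  }
  out <- lapply(unname(groups), function(g) {
    g <- sort(g)
    ord <- order_markers(g, dmat[g, g, drop = FALSE])
    cm <- c(0, cumsum(dmat[cbind(ord[-length(ord)], ord[-1L])]))
    data.frame(marker = ord, cm = cm, stringsAsFactors = FALSE)
  })
  sizes <- vapply(out, nrow, integer(1))
  out[order(-sizes, vapply(out, function(g) g$marker[1L], character(1)))]
}

#' All pairwise marker linkage estimates from a genotype table
#'
#' @param marker_table as from [simulate_marker_table()].
#' @param markers marker columns to use (default all).
#' @return data.frame(a, b, r_hat, lod) for every unordered pair.
#' @export
pairwise_linkage <- function(marker_table, markers = NULL) {
  if (is.null(markers)) {
    markers <- setdiff(names(marker_table), c("id", "phenotype"))
  }
  pairs <- utils::combn(markers, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    est <- estimate_r_markers(marker_table[[pairs[1L, j]]],
                              marker_table[[pairs[2L, j]]])
    data.frame(a = pairs[1L, j], b = pairs[2L, j],
               r_hat = est$r_hat, lod = est$lod,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
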