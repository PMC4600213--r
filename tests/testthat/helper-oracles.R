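# Brute-force oracles, coded independently of the package internals:
# every window and every SNP's hit fraction is enumerated explicitly.

oracle_scan_chrom <- function(g, pos, st) {
  empty <- data.frame(start = integer(), end = integer(),
                      n_snps = integer())
  n <- length(g)
  w <- st$window_snps
  if (n < w) return(empty)
  win_pass <- logical(n - w + 1)
  for (s in seq_len(n - w + 1)) {
    win <- g[s:(s + w - 1)]
    win_pass[s] <- sum(win == 1, na.rm = TRUE) <= st$max_het_per_window &&
      sum(is.na(win)) <= st$max_missing_per_window
  }
  elig <- logical(n)
  for (i in seq_len(n)) {
    covering <- intersect(seq_len(n - w + 1), (i - w + 1):i)
    elig[i] <- mean(win_pass[covering]) >= st$hit_proportion
  }
  segs <- empty
  i <- 1
  while (i <= n) {
    if (!elig[i]) { i <- i + 1; next }
    j <- i
    while (j < n && elig[j + 1]) j <- j + 1
    idx <- i:j
    hom_at <- idx[!is.na(g[idx]) & g[idx] != 1]
    if (length(hom_at) > 0) {
      a <- hom_at[1]
      b <- hom_at[length(hom_at)]
      len <- pos[b] - pos[a] + 1
      ns <- b - a + 1
      len_ok <- if (st$strict_min_length) len > st$min_length_bp else
        len >= st$min_length_bp
      gap_ok <- ns == 1 || max(diff(pos[a:b])) <= st$max_gap_bp
      dens_ok <- (len / 1000) / ns <= st$max_density_kb_per_snp
      if (ns >= st$min_snps_per_segment && len_ok && gap_ok && dens_ok) {
        segs <- rbind(segs, data.frame(start = pos[a], end = pos[b],
                                       n_snps = ns))
      }
    }
    i <- j + 1
  }
  segs
}

# position-by-position interval grouping over the panel's site list
oracle_group <- function(surviving, panel_pos) {
  runs <- list()
  cur <- integer()
  for (p in sort(panel_pos)) {
    if (p %in% surviving) {
      cur <- c(cur, p)
    } else if (length(cur) > 0) {
      runs <- c(runs, list(cur)); cur <- integer()
    }
  }
  if (length(cur) > 0) runs <- c(runs, list(cur))
  data.frame(start = vapply(runs, min, numeric(1)),
             end = vapply(runs, max, numeric(1)),
             n_snps = lengths(runs))
}

oracle_private <- function(sets, target, panel_pos) {
  others <- unlist(sets[setdiff(names(sets), target)], use.names = FALSE)
  surv <- sets[[target]][!sets[[target]] %in% others]
  oracle_group(surv, panel_pos)
}

oracle_shared <- function(sets, in_group, out_group, panel_pos) {
  surv <- Reduce(intersect, sets[in_group])
  if (length(out_group) > 0) {
    surv <- surv[!surv %in% unlist(sets[out_group], use.names = FALSE)]
  }
  oracle_group(surv, panel_pos)
}

# Textbook site-frequency-spectrum statistics, from the original
# publications' constants, written as straight scalar formulas.
# xi: counts of segregating sites with derived-allele count k = 1..n-1.
oracle_neutrality <- function(xi, n) {
  S <- sum(xi)
  ks <- rep(seq_len(n - 1), xi)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)

  tp <- sum(ks * (n - ks)) / choose(n, 2)
  tw <- S / a1
  tl <- sum(ks) / (n - 1)
  th <- sum(ks^2) / choose(n, 2)
  eta_e <- sum(ks == 1)

  # Tajima 1989
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- if (S > 0) (tp - tw) / sqrt(e1 * S + e2 * S * (S - 1)) else NA_real_

  # Fu & Li 1993 with the corrected variance constants
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + a1^2 / (a2 + a1^2) * (cn - (n + 1) / (n - 1))
  uD <- a1 - 1 - vD
  FLD <- if (S > 0) (S - a1 * eta_e) / sqrt(uD * S + vD * S^2) else NA_real_
  an1 <- a1 + 1 / n
  vF <- (cn + 2 * (n * n + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
    (a1^2 + a2)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a1 - vF
  FLF <- if (S > 0) (tp - eta_e) / sqrt(uF * S + vF * S^2) else NA_real_

  # Fay & Wu's H and Zeng's E, normalized as in Zeng et al. 2006
  th_hat <- S / a1
  th2_hat <- S * (S - 1) / (a1^2 + a2)
  bn1 <- a2 + 1 / n^2
  varH <- th_hat * (n - 2) / (6 * (n - 1)) +
    th2_hat * (18 * n^2 * (3 * n + 2) * bn1 -
                 (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  H <- if (S > 0) (tp - tl) / sqrt(varH) else NA_real_
  varE <- th_hat * (n / (2 * (n - 1)) - 1 / a1) +
    th2_hat * (a2 / a1^2 + 2 * (n / (n - 1))^2 * a2 -
                 2 * (n * a2 - n + 1) / ((n - 1) * a1) -
                 (3 * n + 1) / (n - 1))
  E <- if (S > 0) (tl - tw) / sqrt(varE) else NA_real_

  list(S = S, theta_pi = tp, theta_W = tw, theta_L = tl, theta_H = th,
       tajima_D = D, fuli_D = FLD, fuli_F = FLF, fay_H = H, zeng_E = E)
}

# all weak compositions of s into `parts` parts (rows)
compositions <- function(s, parts) {
  if (parts == 1) return(matrix(s, 1, 1))
  out <- list()
  for (first in 0:s) {
    rest <- compositions(s - first, parts - 1)
    out[[first + 1]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# quadratic all-pairs interval/gene overlap oracle
oracle_overlap <- function(intervals, genes) {
  hits <- list()
  for (i in seq_len(nrow(intervals))) {
    for (j in seq_len(nrow(genes))) {
      if (intervals$chrom[i] == genes$chrom[j] &&
          intervals$start[i] <= genes$end[j] &&
          intervals$end[i] >= genes$start[j]) {
        hits[[length(hits) + 1]] <- data.frame(interval_id = i, gene = j)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(interval_id = integer(), gene = integer()))
  }
  do.call(rbind, hits)
}
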