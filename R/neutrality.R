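#' Derived-allele spectrum of a genomic window
#'
#' Treats each diploid genotype as two chromosomes and the reference allele
#' as ancestral (no outgroup being available), so the derived-allele count of
#' a site is its alternate-allele count.  Missing calls reduce the per-site
#' number of called chromosomes; sites with fewer than four called
#' chromosomes are skipped, and only segregating sites
#' (`0 < k < n_called`) are returned.
#'
#' @param panel A filtered [genotype_panel()].
#' @param chrom Chromosome label.
#' @param start,end Window bounds in bp (1-based inclusive).  A window
#'   outside the chromosome's sites is simply empty.
#' @return Tibble with `pos`, `k` (derived-allele count) and `n_called`
#'   (called chromosomes at the site).
#' @export
window_site_spectrum <- function(panel, chrom, start, end) {
  idx <- which(panel$sites$chrom == chrom & panel$sites$pos >= start &
                 panel$sites$pos <= end)
  if (length(idx) == 0) {
    return(tibble::tibble(pos = integer(), k = integer(),
                          n_called = integer()))
  }
  g <- panel$geno[idx, , drop = FALSE]
  k <- rowSums(g, na.rm = TRUE)
  n_called <- 2L * rowSums(!is.na(g))
  seg <- n_called >= 4L & k > 0 & k < n_called
  tibble::tibble(pos = panel$sites$pos[idx][seg],
                 k = as.integer(k[seg]),
                 n_called = as.integer(n_called[seg]))
}

harmonic1 <- function(n) sum(1 / seq_len(n - 1))
harmonic2 <- function(n) sum(1 / seq_len(n - 1)^2)

#' Neutrality test statistics from a site spectrum
#'
#' Computes the Watterson, pairwise, L and H estimators of the population
#' mutation rate and the neutrality tests Tajima's D, Fu & Li's D and F
#' (singleton-based, with the corrected variance constants), the normalized
#' Fay & Wu's H and Zeng's E, from per-site derived-allele counts.
#'
#' With missing data the theta estimators are sums of per-site unbiased
#' terms using each site's own number of called chromosomes, which reduces
#' to the classical single-`n` formulas on complete data; the variance
#' normalizations always use `n_chromosomes`.  Statistics are `NA`
#' (undefined) when `n_chromosomes < 4`, when `S = 0`, or when the relevant
#' variance term is not positive.
#'
#' @param spectrum Tibble from [window_site_spectrum()] (columns `k`,
#'   `n_called`), or an integer vector of derived-allele counts (then
#'   `n_chromosomes` is used for every site).
#' @param n_chromosomes Number of chromosomes (2 x samples with data).
#' @param folded If `TRUE`, the ancestral state is considered unknown:
#'   `theta_pi`, `theta_W` and Tajima's D are still valid (they are
#'   invariant to folding), but the unfolded statistics (Fu & Li, Fay & Wu's
#'   H, Zeng's E) are returned as `NA`.
#' @return A one-row tibble: `n_chromosomes`, `S`, `singletons`, `theta_pi`,
#'   `theta_W`, `theta_L`, `theta_H`, `tajima_D`, `fuli_D`, `fuli_F`,
#'   `fay_H`, `zeng_E`, `defined` (any statistic defined).
#' @export
neutrality_stats <- function(spectrum, n_chromosomes, folded = FALSE) {
  if (is.numeric(spectrum) && is.null(dim(spectrum))) {
    spectrum <- tibble::tibble(k = as.integer(spectrum),
                               n_called = as.integer(n_chromosomes))
  }
  k <- spectrum$k
  nc <- spectrum$n_called
  seg <- k > 0 & k < nc & nc >= 4
  k <- k[seg]; nc <- nc[seg]
  S <- length(k)
  n <- as.integer(n_chromosomes)

  row <- function(singletons = NA_integer_, theta_pi = NA_real_,
                  theta_W = NA_real_, theta_L = NA_real_,
                  theta_H = NA_real_, tajima_D = NA_real_,
                  fuli_D = NA_real_, fuli_F = NA_real_, fay_H = NA_real_,
                  zeng_E = NA_real_) {
    tibble::new_tibble(list(
      n_chromosomes = n, S = S, singletons = as.integer(singletons),
      theta_pi = theta_pi, theta_W = theta_W, theta_L = theta_L,
      theta_H = theta_H, tajima_D = tajima_D, fuli_D = fuli_D,
      fuli_F = fuli_F, fay_H = fay_H, zeng_E = zeng_E,
      defined = !all(is.na(c(tajima_D, fuli_D, fuli_F, fay_H, zeng_E)))),
      nrow = 1L)
  }
  if (n < 4 || S == 0) return(row())

  theta_pi <- sum(2 * k * (nc - k) / (nc * (nc - 1)))
  theta_W <- sum(1 / vapply(nc, harmonic1, numeric(1)))
  theta_L <- sum(k / (nc - 1))
  theta_H <- sum(2 * k^2 / (nc * (nc - 1)))
  eta_e <- sum(k == 1L)

  a1 <- harmonic1(n)
  a2 <- harmonic2(n)
  # Tajima's D
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  vD <- e1 * S + e2 * S * (S - 1)
  tajima_D <- if (vD > 0) (theta_pi - theta_W) / sqrt(vD) else NA_real_
  if (!is.na(tajima_D) && theta_pi == theta_W) tajima_D <- 0

  if (folded) {
    return(row(singletons = eta_e, theta_pi = theta_pi, theta_W = theta_W,
               tajima_D = tajima_D))
  }

  # Fu & Li's D and F (singleton-based, corrected constants)
  cn <- if (n > 2) 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2)) else 1
  v_D <- 1 + (a1^2 / (a2 + a1^2)) * (cn - (n + 1) / (n - 1))
  u_D <- a1 - 1 - v_D
  varFD <- u_D * S + v_D * S^2
  fuli_D <- if (varFD > 0) (S - a1 * eta_e) / sqrt(varFD) else NA_real_

  an1 <- a1 + 1 / n
  v_F <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
    (a1^2 + a2)
  u_F <- (1 + (n + 1) / (3 * (n - 1)) -
            4 * ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / a1 - v_F
  varFF <- u_F * S + v_F * S^2
  fuli_F <- if (varFF > 0) (theta_pi - eta_e) / sqrt(varFF) else NA_real_

  # normalized Fay & Wu's H and Zeng's E
  theta_hat <- S / a1
  theta2_hat <- S * (S - 1) / (a1^2 + a2)
  b2n1 <- a2 + 1 / n^2
  var_H <- theta_hat * (n - 2) / (6 * (n - 1)) +
    theta2_hat * (18 * n^2 * (3 * n + 2) * b2n1 -
                    (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  fay_H <- if (var_H > 0) (theta_pi - theta_L) / sqrt(var_H) else NA_real_

  var_E <- theta_hat * (n / (2 * (n - 1)) - 1 / a1) +
    theta2_hat * (a2 / a1^2 + 2 * (n / (n - 1))^2 * a2 -
                    2 * (n * a2 - n + 1) / ((n - 1) * a1) -
                    (3 * n + 1) / (n - 1))
  zeng_E <- if (var_E > 0) (theta_L - theta_W) / sqrt(var_E) else NA_real_

  row(singletons = eta_e, theta_pi = theta_pi, theta_W = theta_W,
      theta_L = theta_L, theta_H = theta_H, tajima_D = tajima_D,
      fuli_D = fuli_D, fuli_F = fuli_F, fay_H = fay_H, zeng_E = zeng_E)
}

#' Windowed neutrality scan
#'
#' Tiles each chromosome with non-overlapping windows (or a sliding step
#' smaller than the window) and computes the theta estimators and neutrality
#' statistics per window across all samples jointly.  Canonical window sizes
#' for the sequence panels this was built for are 40 kb and 400 kb.
#'
#' @param panel A filtered [genotype_panel()].
#' @param window_bp Window size in bp.
#' @param step_bp Step between window starts; defaults to `window_bp`
#'   (non-overlapping tiles).
#' @param folded Passed to [neutrality_stats()].
#' @return Tibble with `chrom`, `start`, `end` and the columns of
#'   [neutrality_stats()].
#' @export
neutrality_scan <- function(panel, window_bp = 40000, step_bp = window_bp,
                            folded = FALSE) {
  stopifnot(window_bp >= 1, step_bp >= 1)
  out <- list()
  for (ch in unique(panel$sites$chrom)) {
    on_ch <- panel$sites$chrom == ch
    pos <- panel$sites$pos[on_ch]
    g <- panel$geno[on_ch, , drop = FALSE]
    starts <- seq(1L, max(pos), by = step_bp)
    k_all <- rowSums(g, na.rm = TRUE)
    ncall <- 2L * rowSums(!is.na(g))
    for (w0 in starts) {
      w1 <- w0 + window_bp - 1
      lo <- findInterval(w0 - 1, pos) + 1L
      hi <- findInterval(w1, pos)
      if (hi < lo) {
        idx <- integer()
      } else idx <- lo:hi
      n_chrom <- if (length(idx)) {
        2L * sum(colSums(!is.na(g[idx, , drop = FALSE])) > 0)
      } else 0L
      spec <- tibble::tibble(k = as.integer(k_all[idx]),
                             n_called = ncall[idx])
      st <- neutrality_stats(spec, max(n_chrom, 0L), folded = folded)
      out[[length(out) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(chrom = ch, start = w0, end = w1), st)
    }
  }
  dplyr::bind_rows(out)
}

#' Flag neutrality windows inside ROH regions
#'
#' Marks each window with whether it overlaps (by at least 1 bp) any of the
#' supplied intervals, and flags windows that both overlap and show a
#' Tajima's D strictly below the threshold -- the working definition of a
#' deviation from neutrality inside a consensus ROH (values below -1.2 in
#' the motivating analysis).
#'
#' @param windows Tibble from [neutrality_scan()].
#' @param intervals Interval tibble (`chrom`, `start`, `end`), e.g. from
#'   [consensus_rohs()].
#' @param threshold Tajima's D threshold; a window is flagged when
#'   `tajima_D < threshold` (strict).
#' @return `windows` with logical columns `in_roh` and `flagged`.
#' @export
flag_roh_windows <- function(windows, intervals, threshold = -1.2) {
  in_roh <- rep(FALSE, nrow(windows))
  if (!is.null(intervals) && nrow(intervals) > 0) {
    for (k in seq_len(nrow(intervals))) {
      in_roh <- in_roh | (windows$chrom == intervals$chrom[k] &
                            windows$start <= intervals$end[k] &
                            windows$end >= intervals$start[k])
    }
  }
  windows$in_roh <- in_roh
  windows$flagged <- in_roh & !is.na(windows$tajima_D) &
    windows$tajima_D < threshold
  windows
}
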