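# Inclusive composite interval mapping (ICIM) for biparental RIL
# populations, two-step regression form: (1) forward-backward stepwise
# selection of marker cofactors with an entry p-value threshold PIN
# (removal threshold POUT = 2 * PIN); (2) a 1-cM interval scan of the
# cofactor-adjusted phenotype on the expected QTL dosage given the flanking
# marker genotypes (Haley-Knott regression), where the cofactors at the two
# flanking markers of the interval being scanned are excluded from the
# adjustment (the "inclusive" background control). Genotype probabilities
# use the Haldane map function with the RIL correction R = 2r / (1 + 2r).

#' Scan parameters for ICIM QTL mapping
#'
#' @param step_cM scan grid spacing (default 1 cM).
#' @param pin stepwise entry p-value threshold (default 0.01); the removal
#'   threshold is `2 * pin`.
#' @param n_permutations permutations for [permutation_threshold()]
#'   (default 1000).
#' @param lod_min LOD threshold for calling QTLs (default 2.5).
#' @param lod_drop LOD drop defining support intervals (default 2).
#' @param window_cM cofactors within this genetic distance of the scanned
#'   interval are excluded from the background adjustment (default 10 cM);
#'   0 excludes only the flanking markers themselves.
#' @param peak_merge_cM peaks closer than this are merged, keeping the
#'   higher (default 20 cM).
#' @param seed integer seed for the permutation scheme.
#' @return A `scan_params` object.
#' @export
scan_params <- function(step_cM = 1, pin = 0.01, n_permutations = 1000,
                        lod_min = 2.5, lod_drop = 2, peak_merge_cM = 20,
                        window_cM = 10, seed = 1L) {
  stopifnot(step_cM > 0, pin > 0, pin < 1, n_permutations >= 1,
            lod_min >= 0, lod_drop > 0, peak_merge_cM >= 0, window_cM >= 0)
  structure(list(step_cM = step_cM, pin = pin,
                 n_permutations = as.integer(n_permutations),
                 lod_min = lod_min, lod_drop = lod_drop,
                 peak_merge_cM = peak_merge_cM, window_cM = window_cM,
                 seed = as.integer(seed)),
            class = "scan_params")
}

# expected QTL dosage (P(A) - P(B)) at a position between two markers, for
# one line, from flanking codes in {1, -1, NA} and RIL-corrected
# recombination fractions R1 (left-QTL), R2 (QTL-right), R12 (left-right)
dosage_between <- function(gl, gr, R1, R2, R12) {
  n <- length(gl)
  x <- numeric(n)
  both <- !is.na(gl) & !is.na(gr)
  only_l <- !is.na(gl) & is.na(gr)
  only_r <- is.na(gl) & !is.na(gr)
  if (any(both)) {
    same <- both & gl == gr
    diff <- both & gl != gr
    if (R12 <= 0) {
      x[same] <- gl[same]
      x[diff] <- 0                      # inconsistent double at zero distance
    } else {
      x[same] <- gl[same] * ((1 - R1) * (1 - R2) - R1 * R2) / (1 - R12)
      x[diff] <- gl[diff] * ((1 - R1) * R2 - R1 * (1 - R2)) / R12
    }
  }
  x[only_l] <- gl[only_l] * (1 - 2 * R1)
  x[only_r] <- gr[only_r] * (1 - 2 * R2)
  x
}

# precompute the scan grid and dosage matrix for a population; reused by the
# observed scan and by every permutation
scan_design <- function(pop, step_cM = 1) {
  map <- pop$map
  g <- matrix(NA_real_, nrow(pop$genotypes), ncol(pop$genotypes))
  g[pop$genotypes == "A"] <- 1
  g[pop$genotypes == "B"] <- -1
  n <- nrow(g)
  grid <- list(); cols <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    cm <- map$cM[idx]
    pos <- sort(unique(c(seq(min(cm), max(cm), by = step_cM), cm)))
    left <- findInterval(pos, cm, rightmost.closed = TRUE)
    left <- pmin(pmax(left, 1L), length(idx) - 1L)
    right <- left + 1L
    D <- matrix(0, n, length(pos))
    for (k in seq_along(pos)) {
      li <- idx[left[k]]; ri <- idx[right[k]]
      d1 <- pos[k] - cm[left[k]]; d2 <- cm[right[k]] - pos[k]
      R1 <- ril_R(haldane_r(d1)); R2 <- ril_R(haldane_r(d2))
      R12 <- ril_R(haldane_r(cm[right[k]] - cm[left[k]]))
      D[, k] <- dosage_between(g[, li], g[, ri], R1, R2, R12)
    }
    grid[[ch]] <- data.frame(chrom = ch, pos_cM = pos,
                             left = idx[left], right = idx[right],
                             stringsAsFactors = FALSE)
    cols[[ch]] <- D
  }
  grid <- do.call(rbind, grid)
  D <- do.call(cbind, cols)
  key <- paste(grid$left, grid$right)
  groups <- split(seq_len(nrow(grid)), key)
  flanks <- lapply(groups, function(ix) c(grid$left[ix[1]], grid$right[ix[1]]))
  group_chrom <- vapply(groups, function(ix) grid$chrom[ix[1]], character(1))
  group_lo <- vapply(groups, function(ix) map$cM[grid$left[ix[1]]], numeric(1))
  group_hi <- vapply(groups, function(ix) map$cM[grid$right[ix[1]]], numeric(1))
  list(grid = grid, D = D, groups = groups, flanks = flanks,
       group_chrom = group_chrom, group_lo = group_lo, group_hi = group_hi,
       marker_chrom = map$chrom, marker_cM = map$cM, n = n)
}

# forward-backward stepwise with partial-F entry p <= pin, removal p > pout
stepwise_indices <- function(X, y, pin, pout = 2 * pin, k_max = NULL) {
  n <- nrow(X); M <- ncol(X)
  if (is.null(k_max)) k_max <- max(1L, min(M, floor(n / 4)))
  sel <- integer(0)
  backward <- function(sel) {
    while (length(sel) > 0) {
      Xs <- cbind(1, X[, sel, drop = FALSE])
      fit <- stats::lm.fit(Xs, y)
      df <- n - length(sel) - 1L
      if (df <= 0) { sel <- sel[-length(sel)]; next }
      rss <- sum(fit$residuals^2)
      R <- qr.R(fit$qr)
      XtXinv_diag <- diag(chol2inv(R))[-1]
      se <- sqrt(pmax(XtXinv_diag, 0) * rss / df)
      tval <- abs(fit$coefficients[-1] / se)
      tval[!is.finite(tval)] <- Inf
      pvals <- 2 * stats::pt(tval, df, lower.tail = FALSE)
      worst <- which.max(pvals)
      if (pvals[worst] > pout) sel <- sel[-worst] else break
    }
    sel
  }
  seen <- character(0)
  repeat {
    key <- paste(sel, collapse = ",")
    if (key %in% seen) break                    # guard against add/remove cycles
    seen <- c(seen, key)
    k <- length(sel)
    if (k >= k_max) break
    Xs <- if (k) cbind(1, X[, sel, drop = FALSE]) else matrix(1, n, 1)
    qrX <- qr(Xs)
    ry <- qr.resid(qrX, y)
    df <- n - k - 2L
    if (df <= 0 || sum(ry^2) < 1e-12) break
    RX <- qr.resid(qrX, X)
    ssx <- colSums(RX^2)
    sxy <- colSums(RX * ry)
    ssy <- sum(ry^2)
    rho2 <- ifelse(ssx > 1e-10 * n, sxy^2 / (ssx * ssy), 0)
    rho2 <- pmin(rho2, 1 - 1e-12)
    Fv <- df * rho2 / (1 - rho2)
    pv <- stats::pf(Fv, 1, df, lower.tail = FALSE)
    pv[sel] <- Inf
    best <- which.min(pv)                       # first minimum = map order
    if (!is.finite(pv[best]) || pv[best] > pin) break
    sel <- sort(c(sel, best))
    sel <- backward(sel)
  }
  sort(sel)
}

#' Stepwise cofactor selection for ICIM
#'
#' Forward-backward stepwise linear regression of the phenotype on the
#' marker codes (`A = +1`, `B = -1`, missing values mean-imputed per
#' marker). A marker enters when its partial-F p-value is at most `pin` and
#' is removed when it exceeds `2 * pin`. Deterministic; entry ties break
#' toward map order.
#'
#' @param pop a `ril_population`.
#' @param trait phenotype name in `pop$phenotypes`.
#' @param pin entry p-value threshold.
#' @return list with `markers` (names), `index` (map positions),
#'   `coefficients` (joint fit, including intercept), `pin`, `pout`.
#' @export
select_cofactors <- function(pop, trait, pin = 0.01) {
  y <- pop$phenotypes[[trait]]
  if (is.null(y)) stop("unknown trait: ", trait)
  if (stats::var(y) == 0) stop("degenerate error: zero-variance phenotype")
  X <- geno_numeric(pop)
  sel <- stepwise_indices(X, y, pin)
  co <- if (length(sel)) stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)$coefficients
        else stats::lm.fit(cbind(rep(1, length(y))), y)$coefficients
  list(markers = colnames(X)[sel], index = sel,
       coefficients = stats::setNames(co, c("(intercept)", colnames(X)[sel])),
       pin = pin, pout = 2 * pin)
}

# cofactors to exclude when scanning group gi: all selected markers on the
# group's chromosome within window_cM of the interval (flankers are at
# distance zero, so they are always excluded)
excluded_cofactors <- function(design, gi, sel, window_cM) {
  if (length(sel) == 0) return(integer(0))
  ch <- design$group_chrom[gi]
  lo <- design$group_lo[gi] - window_cM
  hi <- design$group_hi[gi] + window_cM
  sel[design$marker_chrom[sel] == ch &
        design$marker_cM[sel] >= lo & design$marker_cM[sel] <= hi]
}

# LOD profile for one phenotype vector given a precomputed design;
# returns the profile vector (and, if wanted, per-position regression stats)
icim_profile <- function(design, X, y, sel, beta, window_cM = 10) {
  n <- design$n
  lod <- numeric(nrow(design$grid))
  betas <- numeric(nrow(design$grid))
  for (gi in seq_along(design$groups)) {
    ix <- design$groups[[gi]]
    keep <- setdiff(sel, excluded_cofactors(design, gi, sel, window_cM))
    yadj <- y
    if (length(keep)) {
      pos_in_sel <- match(keep, sel)
      yadj <- as.vector(y - X[, keep, drop = FALSE] %*% beta[pos_in_sel + 1L])
    }
    yadj <- yadj - mean(yadj)
    ss0 <- sum(yadj^2)
    if (ss0 < 1e-12) next
    Dg <- design$D[, ix, drop = FALSE]
    Dg <- sweep(Dg, 2, colMeans(Dg))
    ssx <- colSums(Dg^2)
    sxy <- as.vector(crossprod(Dg, yadj))
    r2 <- ifelse(ssx > 1e-12, sxy^2 / (ssx * ss0), 0)
    r2 <- pmin(r2, 1 - 1e-15)
    lod[ix] <- n / 2 * log10(1 / (1 - r2))
    betas[ix] <- ifelse(ssx > 1e-12, sxy / ssx, 0)
  }
  list(lod = lod, beta = betas)
}

#' ICIM genome scan
#'
#' Computes the LOD profile over a `step_cM` grid (marker positions
#' included) on every chromosome. At each interval the phenotype is
#' adjusted by the selected cofactors excluding those at the interval's
#' flanking markers, then regressed on the expected QTL dosage given the
#' flanking genotypes; `LOD = n/2 * log10(RSS0 / RSS1)`.
#'
#' @param pop a `ril_population`.
#' @param trait phenotype name.
#' @param params a [scan_params()].
#' @return An `icim_scan` object: list with `profile` (chrom, pos_cM, lod,
#'   add), `trait`, `params`, `cofactors`, `n`, and internal scan state
#'   used by [call_qtls()].
#' @export
icim_scan <- function(pop, trait, params = scan_params()) {
  y <- pop$phenotypes[[trait]]
  if (is.null(y)) stop("unknown trait: ", trait)
  if (stats::var(y) == 0) stop("degenerate error: zero-variance phenotype")
  X <- geno_numeric(pop)
  design <- scan_design(pop, params$step_cM)
  sel <- stepwise_indices(X, y, params$pin)
  beta <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)$coefficients
  pr <- icim_profile(design, X, y, sel, beta, params$window_cM)
  profile <- data.frame(design$grid[, c("chrom", "pos_cM")],
                        lod = pr$lod, add = pr$beta,
                        stringsAsFactors = FALSE)
  structure(list(profile = profile, trait = trait, params = params,
                 cofactors = colnames(X)[sel], n = design$n,
                 .design = design, .X = X, .y = y, .sel = sel, .beta = beta),
            class = "icim_scan")
}

#' @export
print.icim_scan <- function(x, ...) {
  cat(sprintf("<icim_scan> trait '%s': %d positions on %d chromosomes, n = %d\n",
              x$trait, nrow(x$profile), length(unique(x$profile$chrom)), x$n))
  cat(sprintf("  max LOD %.3f at chr %s, %.1f cM; cofactors: %s\n",
              max(x$profile$lod),
              x$profile$chrom[which.max(x$profile$lod)],
              x$profile$pos_cM[which.max(x$profile$lod)],
              if (length(x$cofactors)) paste(x$cofactors, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
summary.icim_scan <- function(object, ...) {
  by_chr <- split(object$profile, object$profile$chrom)
  do.call(rbind, lapply(by_chr, function(d)
    data.frame(chrom = d$chrom[1], max_lod = max(d$lod),
               at_cM = d$pos_cM[which.max(d$lod)], stringsAsFactors = FALSE)))
}

#' @export
plot.icim_scan <- function(x, threshold = x$params$lod_min, ...) {
  pr <- x$profile
  chrs <- unique(pr$chrom)
  offs <- c(0, cumsum(vapply(chrs, function(ch) max(pr$pos_cM[pr$chrom == ch]) + 10,
                             numeric(1))))
  names(offs) <- c(chrs, "end")
  xpos <- pr$pos_cM + offs[pr$chrom]
  graphics::plot(xpos, pr$lod, type = "n", xlab = "genome position (cM)",
                 ylab = "LOD", ...)
  for (ch in chrs) {
    sub <- pr$chrom == ch
    graphics::lines(xpos[sub], pr$lod[sub])
  }
  graphics::abline(h = threshold, lty = 2)
  graphics::abline(v = offs[-1] - 5, col = "grey", lty = 3)
  invisible(x)
}

#' Permutation-based genome-wide LOD threshold
#'
#' Permutes the phenotype (seeded), reruns the full ICIM scan (cofactor
#' reselection included) each time, records the genome-wide maximum LOD,
#' and returns the empirical `1 - alpha` quantile (type-7 interpolation).
#'
#' @param pop a `ril_population`.
#' @param trait phenotype name.
#' @param params a [scan_params()] (`n_permutations`, `seed`).
#' @param alpha genome-wide type-I error rate.
#' @return Numeric threshold; the permuted maxima are attached as
#'   `attr(, "max_lods")`.
#' @export
permutation_threshold <- function(pop, trait, params = scan_params(),
                                  alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  y <- pop$phenotypes[[trait]]
  if (is.null(y)) stop("unknown trait: ", trait)
  X <- geno_numeric(pop)
  design <- scan_design(pop, params$step_cM)
  maxlod <- with_seed(params$seed, {
    vapply(seq_len(params$n_permutations), function(b) {
      yp <- y[sample.int(length(y))]
      sel <- stepwise_indices(X, yp, params$pin)
      beta <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), yp)$coefficients
      max(icim_profile(design, X, yp, sel, beta, params$window_cM)$lod)
    }, numeric(1))
  })
  thr <- stats::quantile(maxlod, 1 - alpha, type = 7, names = FALSE)
  attr(thr, "max_lods") <- maxlod
  thr
}

trait_abbrev <- function(trait) {
  parts <- strsplit(trait, "[^A-Za-z0-9]+")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) >= 2) paste0(toupper(substr(parts, 1, 1)), collapse = "")
  else toupper(substr(trait, 1, 3))
}

cm_to_mb <- function(map, chrom, cm) {
  sub <- map[map$chrom == chrom, ]
  stats::approx(sub$cM, sub$Mb, xout = cm, rule = 2, ties = "ordered")$y
}

#' Call QTLs from an ICIM scan
#'
#' Peaks are grid local maxima with `LOD >= lod_min`; peaks closer than
#' `peak_merge_cM` on a chromosome are merged (higher kept). Support
#' intervals extend to the outermost contiguous grid positions with
#' `LOD >= peak - lod_drop`; physical intervals come from piecewise-linear
#' cM-to-Mb interpolation of the map (clamped at chromosome ends). The
#' additive effect is the Haley-Knott regression coefficient at the peak
#' (half the difference between genotype-class means; parent-A allele
#' positive), and PVE is the phenotypic variance fraction explained at the
#' peak. Names follow the `q` + trait abbreviation + chromosome convention.
#'
#' @param scan an `icim_scan`.
#' @param pop the `ril_population` that was scanned.
#' @param trait phenotype name (defaults to the scanned trait).
#' @param params a [scan_params()] (defaults to the scan's).
#' @return A `qtl_result` data.frame: qtl, chromosome, peak_cM, ci_lo_cM,
#'   ci_hi_cM, ci_lo_Mb, ci_hi_Mb, trait, lod, pve_percent, add.
#' @export
call_qtls <- function(scan, pop, trait = scan$trait, params = scan$params) {
  stopifnot(inherits(scan, "icim_scan"))
  pr <- scan$profile
  if (nrow(pr) == 0) stop("empty profile")
  y <- pop$phenotypes[[trait]]
  ss_tot <- sum((y - mean(y))^2)
  out <- list()
  for (ch in unique(pr$chrom)) {
    sub_ix <- which(pr$chrom == ch)
    lod <- pr$lod[sub_ix]; pos <- pr$pos_cM[sub_ix]
    k <- length(lod)
    if (k == 0) next
    is_peak <- vapply(seq_len(k), function(i) {
      l <- if (i > 1) lod[i - 1] else -Inf
      r <- if (i < k) lod[i + 1] else -Inf
      lod[i] >= params$lod_min && lod[i] >= l && lod[i] > r
    }, logical(1))
    peaks <- which(is_peak)
    if (length(peaks) == 0) next
    # merge peaks closer than peak_merge_cM, keep the higher
    peaks <- peaks[order(-lod[peaks], pos[peaks])]
    kept <- integer(0)
    for (p in peaks)
      if (!any(abs(pos[p] - pos[kept]) < params$peak_merge_cM)) kept <- c(kept, p)
    kept <- sort(kept)
    for (p in kept) {
      thr <- lod[p] - params$lod_drop
      lo <- p; while (lo > 1 && lod[lo - 1] >= thr) lo <- lo - 1
      hi <- p; while (hi < k && lod[hi + 1] >= thr) hi <- hi + 1
      gi <- sub_ix[p]
      # recompute PVE at the peak against total phenotypic variance
      grp <- paste(scan$.design$grid$left[gi], scan$.design$grid$right[gi])
      gidx <- match(grp, names(scan$.design$groups))
      keep <- setdiff(scan$.sel,
                      excluded_cofactors(scan$.design, gidx, scan$.sel,
                                         params$window_cM))
      yadj <- y
      if (length(keep))
        yadj <- as.vector(y - scan$.X[, keep, drop = FALSE] %*%
                            scan$.beta[match(keep, scan$.sel) + 1L])
      yadj <- yadj - mean(yadj)
      xg <- scan$.design$D[, gi] - mean(scan$.design$D[, gi])
      ssx <- sum(xg^2)
      expl <- if (ssx > 1e-12) sum(xg * yadj)^2 / ssx else 0
      pve <- 100 * expl / ss_tot
      out[[length(out) + 1]] <- data.frame(
        qtl = paste0("q", trait_abbrev(trait), ch),
        chromosome = ch,
        peak_cM = pos[p],
        ci_lo_cM = pos[lo], ci_hi_cM = pos[hi],
        ci_lo_Mb = cm_to_mb(pop$map, ch, pos[lo]),
        ci_hi_Mb = cm_to_mb(pop$map, ch, pos[hi]),
        trait = trait,
        lod = lod[p],
        pve_percent = pve,
        add = pr$add[gi],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(qtl = character(0), chromosome = character(0),
               peak_cM = numeric(0), ci_lo_cM = numeric(0),
               ci_hi_cM = numeric(0), ci_lo_Mb = numeric(0),
               ci_hi_Mb = numeric(0), trait = character(0),
               lod = numeric(0), pve_percent = numeric(0), add = numeric(0),
               stringsAsFactors = FALSE)
  class(res) <- c("qtl_result", class(res))
  res
}
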