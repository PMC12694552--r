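# Simulated biparental RIL populations and differential-expression tables,
# used to validate the QTL and candidate-gene stages without genotype or
# sequencing downloads.

#' Build an evenly spaced genetic map
#'
#' @param n_chr number of chromosomes.
#' @param chr_length_cM genetic length per chromosome.
#' @param spacing_cM marker spacing.
#' @param mb_per_cM physical-to-genetic scale used to assign Mb positions.
#' @return A `genetic_map` data.frame (chrom, marker, cM, Mb).
#' @export
make_genetic_map <- function(n_chr = 9, chr_length_cM = 100, spacing_cM = 5,
                             mb_per_cM = 0.4) {
  maps <- lapply(seq_len(n_chr), function(ch) {
    pos <- seq(0, chr_length_cM, by = spacing_cM)
    data.frame(chrom = as.character(ch),
               marker = sprintf("m%d_%03d", ch, seq_along(pos)),
               cM = pos, Mb = pos * mb_per_cM,
               stringsAsFactors = FALSE)
  })
  validate_genetic_map(do.call(rbind, maps))
}

# Haldane map function: cM distance -> recombination fraction
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# RIL (selfed F-infinity) correction of a per-meiosis recombination fraction
ril_R <- function(r) 2 * r / (1 + 2 * r)

#' Simulate a biparental RIL population with planted additive QTLs
#'
#' Genotypes are simulated chromosome-wise as a two-state Markov chain along
#' the ordered markers, with transition probability `R = 2r/(1+2r)` where
#' `r` is the Haldane recombination fraction for the adjacent-marker cM
#' distance (the RIL correction for repeated selfing). Lines are fully
#' inbred: codes are `A`/`B` only. The phenotype is the sum of the planted
#' additive effects (applied at the marker nearest each planted position,
#' coded +1 for `A`, -1 for `B`) plus Gaussian noise scaled so the realized
#' genetic variance fraction equals `heritability`.
#'
#' @param map a `genetic_map`.
#' @param n_lines number of RILs (>= 10).
#' @param qtls `NULL` or data.frame with columns `chrom`, `pos_cM`, `add`;
#'   each position must lie within its chromosome's map range.
#' @param heritability scalar in `[0, 1]`; 0 gives a pure-noise phenotype.
#' @param trait_name name under which the phenotype is stored.
#' @param seed integer seed; the simulation is a pure function of its inputs.
#' @return A `ril_population`: list with `genotypes` (n_lines x n_markers
#'   character matrix of A/B), `phenotypes` (named list of numeric vectors),
#'   `map`, and `qtls`.
#' @export
simulate_ril_population <- function(map, n_lines = 100, qtls = NULL,
                                    heritability = 0.5, trait_name = "trait",
                                    seed = 1L) {
  stopifnot(inherits(map, "genetic_map"))
  if (n_lines < 10) stop("n_lines must be >= 10")
  if (heritability < 0 || heritability > 1) stop("heritability must lie in [0, 1]")
  if (!is.null(qtls)) {
    stopifnot(all(c("chrom", "pos_cM", "add") %in% names(qtls)))
    for (i in seq_len(nrow(qtls))) {
      sub <- map[map$chrom == as.character(qtls$chrom[i]), ]
      if (nrow(sub) == 0) stop("planted QTL on unknown chromosome ", qtls$chrom[i])
      if (qtls$pos_cM[i] < min(sub$cM) || qtls$pos_cM[i] > max(sub$cM))
        stop("planted QTL position outside the map range of chromosome ", qtls$chrom[i])
    }
  }
  with_seed(seed, {
    chroms <- unique(map$chrom)
    geno <- matrix(0, nrow = n_lines, ncol = nrow(map))
    colnames(geno) <- map$marker
    for (ch in chroms) {
      idx <- which(map$chrom == ch)
      g <- matrix(0, n_lines, length(idx))
      g[, 1] <- ifelse(stats::runif(n_lines) < 0.5, 1, -1)
      if (length(idx) > 1) {
        d <- diff(map$cM[idx])
        R <- ril_R(haldane_r(d))
        for (j in seq_along(d)) {
          flip <- stats::runif(n_lines) < R[j]
          g[, j + 1] <- g[, j] * ifelse(flip, -1, 1)
        }
      }
      geno[, idx] <- g
    }
    g_val <- numeric(n_lines)
    if (!is.null(qtls) && nrow(qtls) > 0) {
      for (i in seq_len(nrow(qtls))) {
        sub_idx <- which(map$chrom == as.character(qtls$chrom[i]))
        nearest <- sub_idx[which.min(abs(map$cM[sub_idx] - qtls$pos_cM[i]))]
        g_val <- g_val + qtls$add[i] * geno[, nearest]
      }
    }
    var_g <- stats::var(g_val)
    if (heritability == 0) {
      y <- stats::rnorm(n_lines)
    } else if (var_g == 0) {
      stop("degenerate variance: positive heritability with no genetic variance")
    } else if (heritability == 1) {
      y <- g_val
    } else {
      # make the realized (in-sample) genetic variance fraction exactly equal
      # the target: draw noise, orthogonalize it against the genetic values,
      # and rescale it to the implied error variance
      e <- stats::rnorm(n_lines)
      e <- stats::residuals(stats::lm(e ~ g_val))
      e <- e * sqrt(var_g * (1 - heritability) / (heritability * stats::var(e)))
      y <- g_val + e
    }
    codes <- matrix(ifelse(geno > 0, "A", "B"), nrow = n_lines,
                    dimnames = list(NULL, map$marker))
    structure(list(
      genotypes = codes,
      phenotypes = stats::setNames(list(as.numeric(y)), trait_name),
      map = map,
      qtls = qtls
    ), class = "ril_population")
  })
}

#' @export
print.ril_population <- function(x, ...) {
  cat(sprintf("<ril_population> %d lines, %d markers on %d chromosomes\n",
              nrow(x$genotypes), ncol(x$genotypes), length(unique(x$map$chrom))))
  cat("  phenotypes:", paste(names(x$phenotypes), collapse = ", "), "\n")
  if (!is.null(x$qtls) && nrow(x$qtls) > 0)
    cat(sprintf("  planted QTLs: %d\n", nrow(x$qtls)))
  invisible(x)
}

# genotype codes -> numeric +1/-1 with per-marker mean imputation of NAs
geno_numeric <- function(pop) {
  g <- matrix(NA_real_, nrow(pop$genotypes), ncol(pop$genotypes),
              dimnames = dimnames(pop$genotypes))
  g[pop$genotypes == "A"] <- 1
  g[pop$genotypes == "B"] <- -1
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  }
  g
}

#' Simulate a differential-expression table with planted interval genes
#'
#' Genes are placed uniformly along the physical coordinates of the
#' chromosomes; `n_planted` of them are placed inside the supplied QTL
#' intervals (spread evenly across each interval, endpoints included) and
#' given `|log2FC| >= 1` with `p < 0.05`; every other gene is guaranteed to
#' fail that filter.
#'
#' @param n_genes total number of genes.
#' @param qtl_intervals data.frame with columns `chrom`, `start_mb`,
#'   `end_mb` (and optionally `qtl`); must lie within the chromosome bounds.
#' @param n_planted number of planted differentially expressed genes
#'   (`<= n_genes`).
#' @param chrom_lengths_mb named numeric vector of chromosome lengths (Mb).
#' @param seed integer seed.
#' @return A DEG data.frame (gene_id, chrom, pos_mb, log2fc, pvalue,
#'   direction, planted).
#' @export
simulate_deg_table <- function(n_genes, qtl_intervals, n_planted,
                               chrom_lengths_mb = stats::setNames(rep(40, 9), as.character(1:9)),
                               seed = 1L) {
  stopifnot(n_planted <= n_genes, n_planted >= 0)
  if (n_planted > 0) {
    stopifnot(is.data.frame(qtl_intervals), nrow(qtl_intervals) >= 1,
              all(c("chrom", "start_mb", "end_mb") %in% names(qtl_intervals)))
    for (i in seq_len(nrow(qtl_intervals))) {
      ch <- as.character(qtl_intervals$chrom[i])
      if (!ch %in% names(chrom_lengths_mb))
        stop("coordinate error: interval on unknown chromosome ", ch)
      if (qtl_intervals$start_mb[i] < 0 ||
          qtl_intervals$end_mb[i] > chrom_lengths_mb[[ch]] ||
          qtl_intervals$start_mb[i] > qtl_intervals$end_mb[i])
        stop("coordinate error: interval outside chromosome bounds on ", ch)
    }
  }
  with_seed(seed, {
    chroms <- names(chrom_lengths_mb)
    ch <- sample(chroms, n_genes, replace = TRUE,
                 prob = chrom_lengths_mb / sum(chrom_lengths_mb))
    pos <- stats::runif(n_genes, 0, chrom_lengths_mb[ch])
    lfc <- stats::rnorm(n_genes, 0, 0.6)
    p <- stats::runif(n_genes)
    # null genes must fail the DEG filter
    viol <- abs(lfc) >= 1 & p < 0.05
    p[viol] <- stats::runif(sum(viol), 0.05, 1)
    planted <- rep(FALSE, n_genes)
    if (n_planted > 0) {
      take <- seq_len(n_planted)
      iv <- rep(seq_len(nrow(qtl_intervals)), length.out = n_planted)
      for (k in seq_len(n_planted)) {
        i <- iv[k]
        n_in <- sum(iv == i)
        rank_in <- sum(iv[seq_len(k)] == i)
        span <- c(qtl_intervals$start_mb[i], qtl_intervals$end_mb[i])
        pos[take[k]] <- if (n_in == 1) mean(span) else
          seq(span[1], span[2], length.out = n_in)[rank_in]
        ch[take[k]] <- as.character(qtl_intervals$chrom[i])
      }
      lfc[take] <- sample(c(-1, 1), n_planted, replace = TRUE) *
        (1 + stats::rexp(n_planted, 1.5))
      p[take] <- stats::runif(n_planted, 1e-8, 0.049)
      planted[take] <- TRUE
    }
    df <- data.frame(
      gene_id = sprintf("gene_%05d", seq_len(n_genes)),
      chrom = unname(ch), pos_mb = unname(pos),
      log2fc = lfc, pvalue = p,
      direction = ifelse(lfc >= 0, "up", "down"),
      planted = planted,
      stringsAsFactors = FALSE
    )
    df
  })
}
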