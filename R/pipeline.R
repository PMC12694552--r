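# End-to-end pipeline driver: simulate -> segment -> traits -> stats ->
# qtl -> candidates, with a YAML run configuration, per-stage outputs, and
# a manifest of produced files with content digests. Each stage is also
# runnable standalone given its declared inputs; there is no hidden state.

default_run_config <- function() {
  list(
    out_dir = "grainscan_run",
    seed = 1L,
    stages = c("simulate", "segment", "traits", "stats", "qtl", "candidates"),
    simulate = list(
      n_lines = 20L, grains_per_line = 1L, variation_cv = 0.10,
      phantom = list(), heritability = 0.5,
      map = list(n_chr = 9L, chr_length_cM = 100, spacing_cM = 5, mb_per_cM = 0.4),
      qtls = NULL,
      deg = list(n_genes = 500L, n_planted = 7L,
                 intervals = list(list(chrom = "2", start_mb = 25.180, end_mb = 28.330)))
    ),
    segment = list(params = list(), overrides = list()),
    traits = list(aggregate = "mean"),
    stats = list(),
    qtl = list(trait = "K-Volume", step_cM = 1, pin = 0.01,
               n_permutations = 1000, lod_min = 2.5, lod_drop = 2),
    candidates = list(min_abs_log2fc = 1, max_p = 0.05)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.null(names(user[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a pipeline run configuration
#'
#' YAML file of stage parameters; unspecified keys fall back to package
#' defaults. See [run_pipeline()].
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

log_msg <- function(...) message(sprintf("[grainscan] %s", sprintf(...)))

#' Run the grain phenotyping pipeline
#'
#' Executes the requested stages in dependency order
#' (`simulate, segment, traits, stats, qtl, candidates`) under `out_dir`,
#' writes every product as CSV or slice stacks, and finishes with a
#' `manifest.csv` listing each produced file with its MD5 digest.
#' Identical configuration and seed reproduce identical digests for the
#' deterministic stages. A stage failure aborts with the failing stage
#' named and leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config a configuration list from [read_run_config()] (or a path
#'   to a YAML file).
#' @param out_dir output directory; overrides the config when non-NULL.
#' @param seed global seed; overrides the config when non-NULL.
#' @return Invisibly, the manifest data.frame (stage, file, md5).
#' @export
run_pipeline <- function(config = read_run_config(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(default_run_config(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  produced <- list()
  note <- function(stage, files) produced[[length(produced) + 1]] <<-
    data.frame(stage = stage, file = files, stringsAsFactors = FALSE)

  run_stage <- function(stage, fn) {
    log_msg("stage %s ...", stage)
    tryCatch(fn(), error = function(e) {
      writeLines(paste(stage, conditionMessage(e)), file.path(cfg$out_dir, "FAILED"))
      stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stages <- intersect(c("simulate", "segment", "traits", "stats", "qtl", "candidates"),
                      cfg$stages)

  if ("simulate" %in% stages) run_stage("simulate", function() {
    sc <- cfg$simulate
    spec <- do.call(phantom_spec, c(sc$phantom, list(seed = cfg$seed)))
    n_grains <- sc$n_lines * sc$grains_per_line
    cohort <- make_phantom_cohort(spec, n_grains, sc$variation_cv, seed = cfg$seed)
    stack_dir <- file.path(cfg$out_dir, "stacks")
    truth_dir <- file.path(cfg$out_dir, "labels_truth")
    truth <- list()
    for (i in seq_along(cohort)) {
      line <- sprintf("L%03d", (i - 1) %/% sc$grains_per_line + 1)
      grain <- sprintf("g%d", (i - 1) %% sc$grains_per_line + 1)
      sdir <- file.path(stack_dir, line, grain)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      vol <- cohort[[i]]$volume
      for (z in seq_len(dim(vol$data)[1])) {
        sl <- matrix(vol$data[z, , ], dim(vol$data)[2], dim(vol$data)[3])
        tiff::writeTIFF(sl / 65535, file.path(sdir, sprintf("slice_%05d.tif", z - 1)),
                        bits.per.sample = 16)
      }
      write_label_volume(cohort[[i]]$labels, file.path(truth_dir, line, grain))
      tr <- cohort[[i]]$truth
      tr$line_id <- line; tr$grain_id <- grain
      truth[[i]] <- tr
    }
    truth_csv <- file.path(cfg$out_dir, "truth_traits.csv")
    utils::write.csv(do.call(rbind, truth), truth_csv, row.names = FALSE)
    map <- do.call(make_genetic_map, sc$map)
    qtls <- if (!is.null(sc$qtls)) do.call(rbind, lapply(sc$qtls, as.data.frame))
    h <- if (is.null(qtls)) 0 else sc$heritability   # no planted QTLs: pure noise
    pop <- simulate_ril_population(map, sc$n_lines, qtls,
                                   heritability = h, seed = cfg$seed)
    map_csv <- file.path(cfg$out_dir, "map.csv")
    utils::write.csv(as.data.frame(unclass(map))[c("chrom", "marker", "cM", "Mb")],
                     map_csv, row.names = FALSE)
    geno_csv <- file.path(cfg$out_dir, "geno.csv")
    geno_df <- data.frame(line_id = sprintf("L%03d", seq_len(sc$n_lines)),
                          pop$genotypes, check.names = FALSE)
    utils::write.csv(geno_df, geno_csv, row.names = FALSE)
    iv <- do.call(rbind, lapply(cfg$simulate$deg$intervals, as.data.frame))
    degs <- simulate_deg_table(sc$deg$n_genes, iv, sc$deg$n_planted,
                               stats::setNames(rep(sc$map$chr_length_cM * sc$map$mb_per_cM,
                                                   sc$map$n_chr),
                                               as.character(seq_len(sc$map$n_chr))),
                               seed = cfg$seed)
    deg_csv <- file.path(cfg$out_dir, "degs.csv")
    utils::write.csv(degs[, c("gene_id", "chrom", "pos_mb", "log2fc", "pvalue")],
                     deg_csv, row.names = FALSE)
    note("simulate", c(truth_csv, map_csv, geno_csv, deg_csv))
  })

  if ("segment" %in% stages) run_stage("segment", function() {
    params <- do.call(segmentation_params, cfg$segment$params)
    stack_dir <- file.path(cfg$out_dir, "stacks")
    label_dir <- file.path(cfg$out_dir, "labels")
    vox <- do.call(phantom_spec, c(cfg$simulate$phantom, list(seed = cfg$seed)))$voxel_size_um
    grains <- list.dirs(stack_dir, recursive = TRUE)
    grains <- grains[vapply(grains, function(d)
      length(list.files(d, pattern = "\\.tif$")) > 0, logical(1))]
    written <- character(0)
    for (d in grains) {
      vol <- read_slice_stack(d, vox)
      lv <- segment_grain(vol, params, overrides = cfg$segment$overrides)
      rel <- sub(paste0("^", stack_dir, "/?"), "", d)
      write_label_volume(lv, file.path(label_dir, rel))
      written <- c(written, file.path(label_dir, rel, "metadata.txt"))
    }
    note("segment", written)
  })

  if ("traits" %in% stages) run_stage("traits", function() {
    label_dir <- file.path(cfg$out_dir, "labels")
    if (!dir.exists(label_dir)) label_dir <- file.path(cfg$out_dir, "labels_truth")
    dirs <- list.dirs(label_dir, recursive = TRUE)
    dirs <- dirs[file.exists(file.path(dirs, "metadata.txt"))]
    rows <- lapply(dirs, function(d) {
      lv <- read_label_volume(d)
      parts <- strsplit(sub(paste0("^", label_dir, "/?"), "", d), "/")[[1]]
      compute_traits(lv, line_id = parts[1],
                     grain_id = if (length(parts) > 1) parts[2] else NA)
    })
    per_grain <- do.call(rbind, rows)
    grain_csv <- file.path(cfg$out_dir, "traits_per_grain.csv")
    utils::write.csv(per_grain, grain_csv, row.names = FALSE)
    aggfun <- if (identical(cfg$traits$aggregate, "median")) stats::median else mean
    per_line <- do.call(rbind, lapply(split(per_grain, per_grain$line_id), function(g) {
      vals <- lapply(g[TRAIT_COLUMNS], aggfun)
      cbind(data.frame(line_id = g$line_id[1], stringsAsFactors = FALSE),
            as.data.frame(vals, check.names = FALSE))
    }))
    line_csv <- file.path(cfg$out_dir, "traits.csv")
    utils::write.csv(per_line, line_csv, row.names = FALSE)
    note("traits", c(grain_csv, line_csv))
  })

  if ("stats" %in% stages) run_stage("stats", function() {
    traits <- read_trait_table(file.path(cfg$out_dir, "traits.csv"))
    summ <- summarize_traits(traits)
    sum_csv <- file.path(cfg$out_dir, "summary.csv")
    utils::write.csv(summ, sum_csv, row.names = FALSE)
    corr <- correlation_matrix(traits)
    corr_csv <- file.path(cfg$out_dir, "corr.csv")
    utils::write.csv(corr$r, corr_csv, row.names = TRUE)
    pairs <- which(upper.tri(corr$r), arr.ind = TRUE)
    long <- data.frame(trait_a = rownames(corr$r)[pairs[, 1]],
                       trait_b = colnames(corr$r)[pairs[, 2]],
                       r = corr$r[pairs], p = corr$p[pairs],
                       stringsAsFactors = FALSE)
    pair_csv <- file.path(cfg$out_dir, "corr_pairs.csv")
    utils::write.csv(long, pair_csv, row.names = FALSE)
    note("stats", c(sum_csv, corr_csv, pair_csv))
  })

  if ("qtl" %in% stages) run_stage("qtl", function() {
    map <- read_genetic_map(file.path(cfg$out_dir, "map.csv"))
    geno <- read_genotype_matrix(file.path(cfg$out_dir, "geno.csv"))
    traits <- read_trait_table(file.path(cfg$out_dir, "traits.csv"))
    traits <- traits[match(geno$line_id, traits$line_id), ]
    trait <- cfg$qtl$trait
    codes <- as.matrix(geno[, setdiff(names(geno), "line_id")])
    pop <- structure(list(
      genotypes = codes,
      phenotypes = stats::setNames(list(traits[[trait]]), trait),
      map = map, qtls = NULL), class = "ril_population")
    params <- scan_params(step_cM = cfg$qtl$step_cM, pin = cfg$qtl$pin,
                          n_permutations = cfg$qtl$n_permutations,
                          lod_min = cfg$qtl$lod_min, lod_drop = cfg$qtl$lod_drop,
                          seed = cfg$seed)
    scan <- icim_scan(pop, trait, params)
    thr <- permutation_threshold(pop, trait, params, alpha = 0.05)
    calls <- call_qtls(scan, pop)
    log_msg("qtl: max LOD %.3f, permutation threshold %.3f, %d call(s)",
            max(scan$profile$lod), thr, nrow(calls))
    qtl_csv <- file.path(cfg$out_dir, "qtl.csv")
    out <- data.frame(QTL = calls$qtl, Chromosome = calls$chromosome,
                      `Physical Interval (Mb)` = sprintf("%.3f-%.3f",
                                                         calls$ci_lo_Mb, calls$ci_hi_Mb),
                      Traits = calls$trait, LOD = calls$lod,
                      `PVE (%)` = calls$pve_percent, Add = calls$add,
                      check.names = FALSE)
    utils::write.csv(out, qtl_csv, row.names = FALSE)
    thr_csv <- file.path(cfg$out_dir, "lod_threshold.csv")
    utils::write.csv(data.frame(alpha = 0.05, threshold = as.numeric(thr)),
                     thr_csv, row.names = FALSE)
    intern <- calls
    utils::write.csv(intern, file.path(cfg$out_dir, "qtl_internal.csv"), row.names = FALSE)
    note("qtl", c(qtl_csv, thr_csv, file.path(cfg$out_dir, "qtl_internal.csv")))
  })

  if ("candidates" %in% stages) run_stage("candidates", function() {
    qtl_csv <- file.path(cfg$out_dir, "qtl_internal.csv")
    degs <- read_deg_table(file.path(cfg$out_dir, "degs.csv"))
    cand_csv <- file.path(cfg$out_dir, "candidates.csv")
    if (file.exists(qtl_csv)) {
      qtls <- utils::read.csv(qtl_csv, stringsAsFactors = FALSE)
    } else qtls <- data.frame()
    kept <- filter_degs(degs, cfg$candidates$min_abs_log2fc, cfg$candidates$max_p)
    cand <- intersect_qtl_degs(qtls, kept)
    utils::write.csv(cand, cand_csv, row.names = FALSE)
    note("candidates", cand_csv)
  })

  manifest <- if (length(produced)) do.call(rbind, produced) else
    data.frame(stage = character(0), file = character(0))
  manifest <- manifest[file.exists(manifest$file), , drop = FALSE]
  manifest$md5 <- unname(tools::md5sum(manifest$file))
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"), row.names = FALSE)
  log_msg("done: %d file(s) in manifest", nrow(manifest))
  invisible(manifest)
}
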