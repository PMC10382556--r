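# Pipeline orchestration: one configuration drives merge -> QC ->
# diversity/structure/Ne/ROH -> all pairwise selection scans -> annotation,
# with deterministic per-stage seeds and a run manifest. A small subcommand
# CLI wraps the same entry points.

#' Default pipeline configuration
#'
#' All thresholds default to the package's standard values: call rate 0.90,
#' MAF 0.01, HWE 1e-6, PI_HAT 0.25, LD pruning 50/5 with r2 0.5 (PCA
#' subset) and 0.3 (relatedness subset), ROH parameters from
#' [roh_params()], 40-kbps annotation flank, FDR 0.05.
#'
#' @param input list describing the input: either
#'   `list(kind = "simulate", sim = sim_config(...))` or
#'   `list(kind = "plink", ped = ..., map = ...)` /
#'   `list(kind = "vcf", vcf = ..., phased_vcf = ..., populations = ...)`.
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param ... overrides for any default parameter block.
#' @return configuration list.
#' @export
pipeline_config <- function(input, out_dir, seed = 1L, ...) {
  cfg <- list(input = input, out_dir = out_dir, seed = as.integer(seed),
              qc = list(min_rate = 0.90, min_maf = 0.01, hwe_alpha = 1e-6,
                        max_pi_hat = 0.25),
              ld_prune = list(window_snps = 50L, step_snps = 5L,
                              r2_pca = 0.5, r2_rel = 0.3),
              roh = roh_params(),
              scan = scan_config(seed = derive_seed(seed, "scan")),
              ne = list(maf_screens = c(0, 0.02, 0.05, 0.1)),
              annotation = list(flank_bp = 40000, features = NULL,
                                gene_sets = NULL, universe = NULL),
              fdr = 0.05)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- utils::modifyList(cfg[[nm]] %||% list(), over[[nm]])
  cfg
}

#' @keywords internal
#' @noRd
load_pipeline_input <- function(cfg) {
  inp <- cfg$input
  if (is.null(inp$kind)) ps_stop("pipeline config: input$kind missing")
  if (inp$kind == "simulate") {
    ds <- simulate_dataset(inp$sim)
    list(genotypes = ds$genotypes, haplotypes = ds$haplotypes, truth = ds$truth)
  } else if (inp$kind == "plink") {
    for (f in c("ped", "map")) if (is.null(inp[[f]]))
      ps_stop("pipeline config: input$%s missing", f)
    list(genotypes = read_plink_text(inp$ped, inp$map), haplotypes = NULL)
  } else if (inp$kind == "vcf") {
    if (is.null(inp$vcf)) ps_stop("pipeline config: input$vcf missing")
    g <- read_vcf(inp$vcf, population = inp$populations %||% "pop1")
    h <- if (!is.null(inp$phased_vcf))
      read_vcf(inp$phased_vcf, require_phased = TRUE,
               population = inp$populations %||% "pop1") else NULL
    list(genotypes = g, haplotypes = h)
  } else ps_stop("pipeline config: unknown input kind '%s'", inp$kind)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order (QC cascade, LD-pruned subsets, diversity
#' distances and FST, PCA + outlier screen, IBS clustering, LD decay,
#' contemporary and historical Ne, ROH, all pairwise selection scans,
#' optional annotation), writes each result table under `out_dir` and
#' returns the results with a manifest.
#'
#' @param cfg from [pipeline_config()].
#' @param verbose print stage progress.
#' @return list of stage results plus `manifest`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  t0 <- Sys.time()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_times <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    ps_msg(verbose, "[%s] ...", name)
    res <- tryCatch(expr, error = function(e)
      ps_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    stage_times[[name]] <<- round(as.numeric(Sys.time() - ts, units = "secs"), 2)
    res
  }

  inp <- stage("input", load_pipeline_input(cfg))
  g_raw <- inp$genotypes

  qc <- stage("qc", qc_cascade(g_raw, cfg$qc$min_rate, cfg$qc$min_maf,
                               cfg$qc$hwe_alpha, cfg$qc$max_pi_hat))
  g <- qc$genotypes
  qc_tab <- do.call(rbind, lapply(qc$reports, function(r)
    data.frame(step = r$step, n_snps_removed = r$n_snps_removed,
               n_samples_removed = r$n_samples_removed,
               n_snps_out = r$n_snps_out, n_samples_out = r$n_samples_out)))
  write_tsv(qc_tab, file.path(cfg$out_dir, "qc_report.tsv"))

  pruned_pca <- stage("ld_prune_pca",
                      ld_prune(g, cfg$ld_prune$window_snps,
                               cfg$ld_prune$step_snps, cfg$ld_prune$r2_pca))
  pruned_rel <- stage("ld_prune_rel",
                      ld_prune(g, cfg$ld_prune$window_snps,
                               cfg$ld_prune$step_snps, cfg$ld_prune$r2_rel))

  freqs <- stage("allele_frequencies", allele_frequencies(g))
  pops <- freqs$populations
  div <- stage("diversity", {
    out <- list(chord = distance_matrix(freqs, "chord"),
                afd = distance_matrix(freqs, "afd_mean"),
                reynolds = distance_matrix(freqs, "reynolds"))
    fst_rows <- list()
    if (length(pops) >= 2L) {
      prs <- utils::combn(pops, 2)
      for (i in seq_len(ncol(prs))) {
        f <- pairwise_fst_multilocus(g, prs[1, i], prs[2, i],
                                     seed = derive_seed(cfg$seed, "fst_boot"))
        fst_rows[[i]] <- data.frame(pop1 = prs[1, i], pop2 = prs[2, i],
                                    fst = f$theta, ci_low = f$ci_low,
                                    ci_high = f$ci_high)
      }
    }
    out$fst <- do.call(rbind, fst_rows)
    out
  })
  if (!is.null(div$fst)) write_tsv(div$fst, file.path(cfg$out_dir, "pairwise_fst.tsv"))
  for (nm in c("chord", "afd", "reynolds"))
    utils::write.table(div[[nm]], file.path(cfg$out_dir, paste0("dist_", nm, ".tsv")),
                       sep = "\t", quote = FALSE)

  struct <- stage("structure", {
    k <- max(3L, min(10L, nrow(pruned_pca$genotypes$dosage) - 1L,
                     ncol(pruned_pca$genotypes$dosage) - 1L))
    pc <- pca_genotypes(pruned_pca$genotypes, k = k)
    lof <- lof_outliers(pc$scores[, 1:3, drop = FALSE],
                        pruned_pca$genotypes$samples$population)
    dis <- ibs_dissimilarity(pruned_rel$genotypes)
    hc <- hierarchical_tree(dis)
    list(pca = pc, lof = lof, dissimilarity = dis, tree = hc)
  })
  write_tsv(struct$lof, file.path(cfg$out_dir, "lof_outliers.tsv"))
  write_tsv(data.frame(sample_id = rownames(struct$pca$scores),
                       struct$pca$scores),
            file.path(cfg$out_dir, "pca_scores.tsv"))
  tree_newick(struct$tree, file.path(cfg$out_dir, "ibs_tree.nwk"))

  lddecay <- stage("ld_decay", ld_decay_curve(g))
  write_tsv(lddecay, file.path(cfg$out_dir, "ld_decay.tsv"))

  ne <- stage("ne", {
    cont <- tryCatch(contemporary_ldne_batch(g, maf_screens = cfg$ne$maf_screens),
                     error = function(e) NULL)
    hist <- lapply(stats::setNames(pops, pops), function(pp)
      tryCatch(historical_ne(g, pp), error = function(e) NULL))
    list(contemporary = cont, historical = hist)
  })
  if (!is.null(ne$contemporary))
    write_tsv(ne$contemporary, file.path(cfg$out_dir, "ne_contemporary.tsv"))

  roh <- stage("roh", {
    segs <- detect_roh(g, params = cfg$roh)
    summ <- roh_summary(g, segs)
    list(segments = segs, summary = summ)
  })
  write_tsv(roh$segments, file.path(cfg$out_dir, "roh_segments.tsv"))
  write_tsv(roh$summary$froh, file.path(cfg$out_dir, "froh.tsv"))

  scans <- list()
  if (!is.null(inp$haplotypes) && length(pops) >= 2L) {
    prs <- utils::combn(pops, 2)
    for (i in seq_len(ncol(prs))) {
      nm <- paste0(prs[1, i], "_vs_", prs[2, i])
      scans[[nm]] <- stage(paste0("scan_", nm),
                           run_pairwise_scan(g, inp$haplotypes, prs[1, i],
                                             prs[2, i], cfg$scan))
      write_tsv(scans[[nm]], file.path(cfg$out_dir, paste0("scan_", nm, ".tsv")))
    }
  }

  annot <- NULL
  if (!is.null(cfg$annotation$features) && length(scans)) {
    annot <- stage("annotation", {
      lapply(scans, function(sc) {
        sig <- sc[sc$significant, c("snp_id", "chrom", "pos"), drop = FALSE]
        overlap_features(sig, cfg$annotation$features,
                         cfg$annotation$flank_bp,
                         variants = sc[, c("snp_id", "chrom", "pos")])
      })
    })
  }

  manifest <- list(package_version = as.character(utils::packageVersion("popsweep")),
                   r_version = R.version.string,
                   seed = cfg$seed,
                   stages = names(stage_times),
                   stage_seconds = stage_times,
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   total_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(genotypes = g, qc = qc, diversity = div, structure = struct,
                 ld_decay = lddecay, ne = ne, roh = roh, scans = scans,
                 annotation = annot, manifest = manifest, truth = inp$truth))
}

#' Build the packaged demo dataset and run the pipeline on it
#'
#' Four populations with sample sizes 21/29/67/52 (mirroring a typical
#' multi-breed panel), desk-scale genome, full pipeline output for
#' regression testing.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_snps_per_chrom,n_chromosomes demo genome size. The defaults keep
#'   a ~25 kbps marker spacing on a 15-Mbps chromosome so the xp-EHH
#'   integration (gap rule, truncation below 0.05) stays defined.
#' @return the [run_pipeline()] result, invisibly.
#' @export
make_demo <- function(out_dir, seed = 1L, n_snps_per_chrom = 600L,
                      n_chromosomes = 2L) {
  sim <- sim_config(seed = derive_seed(seed, "demo"), n_populations = 4L,
                    ne = 200L, generations = 40L,
                    n_chromosomes = n_chromosomes,
                    chrom_length_bp = 1.5e7,
                    n_snps_per_chrom = n_snps_per_chrom,
                    sample_sizes = c(21L, 29L, 67L, 52L))
  cfg <- pipeline_config(list(kind = "simulate", sim = sim), out_dir,
                         seed = seed)
  run_pipeline(cfg)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run-all`, `demo`. `simulate` writes a simulated
#' dataset (PLINK text + phased VCF + truth); `run-all` runs the pipeline on
#' a simulated dataset; `demo` runs [make_demo()]. Invoke via
#' `Rscript -e 'popsweep::cli_main()' <subcommand> --seed 1 --out dir`.
#'
#' @param args command-line arguments (default: from the process).
#' @return exit status 0 invisibly; stops with a message on bad usage.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    ps_stop("usage: <simulate|run-all|demo> [--seed N] [--out DIR] [--snps N] [--pops N]")
  sub <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "popsweep_out"),
    optparse::make_option("--snps", type = "integer", default = 300L),
    optparse::make_option("--pops", type = "integer", default = 2L)))
  opt <- optparse::parse_args(parser, args = args[-1])
  if (sub == "simulate") {
    ds <- simulate_dataset(sim_config(seed = opt$seed, n_populations = opt$pops,
                                      n_snps_per_chrom = opt$snps))
    export_dataset(ds, opt$out, "plink_text")
    export_dataset(ds, opt$out, "vcf_phased")
    message("wrote simulated dataset to ", opt$out)
  } else if (sub == "run-all") {
    sim <- sim_config(seed = derive_seed(opt$seed, "cli"),
                      n_populations = opt$pops, n_snps_per_chrom = opt$snps)
    cfg <- pipeline_config(list(kind = "simulate", sim = sim), opt$out,
                           seed = opt$seed)
    run_pipeline(cfg)
    message("pipeline outputs in ", opt$out)
  } else if (sub == "demo") {
    make_demo(opt$out, seed = opt$seed, n_snps_per_chrom = opt$snps)
    message("demo outputs in ", opt$out)
  } else ps_stop("unknown subcommand '%s'", sub)
  invisible(0L)
}
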