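## End-to-end pipeline: simulate -> SssI control -> digest -> size-select ->
## array -> normalize -> classify -> segment -> summarize -> tracks ->
## bisulfite validation -> optional two-condition comparison. Every stage
## writes plain-text outputs; a JSON manifest records the configuration,
## seed, package version, per-file md5 digests and timestamps.

#' Run the full McrBC-array pipeline on a simulated genome
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param params a [digest_params()].
#' @param probe_spacing probe grid spacing in bp.
#' @param probe_footprint probe footprint in bp.
#' @param bis_coverage fold coverage for the bisulfite validation of the
#'   first truth HYPO domain (skipped when there is none).
#' @param treat_domain optional index of a truth HYPO domain to re-methylate
#'   as an in-silico "treated" condition; triggers the differential stage.
#' @param enbloc_delta verdict band for [detect_enbloc()].
#' @return invisibly, a list with the manifest and key in-memory results.
#' @export
run_pipeline <- function(config, out_dir, params = digest_params(),
                         probe_spacing = 5000L, probe_footprint = 60L,
                         bis_coverage = 30, treat_domain = NULL,
                         enbloc_delta = 0.2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  path <- function(f) file.path(out_dir, f)

  model <- simulate_genome(config)
  write_fasta(model$sequences, path("genome.fasta"))
  td <- model$truth_domains
  write_bed(data.frame(chrom = td$chrom, start = td$start, end = td$end,
                       name = td$label), path("truth_domains.bed"))
  meth_bg <- do.call(rbind, lapply(names(model$cpg), function(chrom)
    data.frame(chrom = chrom, start = model$cpg[[chrom]]$pos,
               end = model$cpg[[chrom]]$pos + 2L,
               value = model$cpg[[chrom]]$meth)))
  write_bedgraph(meth_bg, path("methylation.bedgraph"))
  write_tsv_report(model$genes, path("genes.tsv"))
  write_bedgraph(mark_track(model$marks, "h3k9ac"), path("h3k9ac.bedgraph"))
  write_bedgraph(mark_track(model$marks, "h3k27me3"),
                 path("h3k27me3.bedgraph"))

  ## digestion + SssI-treated control
  frags <- mcrbc_digest(model, params)
  write_bed(frags, path("fragments.bed"))
  write_tsv_report(fragment_length_hist(frags), path("gel_histogram.tsv"))
  resistant <- size_select(frags, params$size_threshold)
  write_bed(resistant, path("resistant_fragments.bed"))
  sssi_resistant <- size_select(mcrbc_digest(apply_sssi(model), params),
                                params$size_threshold)
  write_bed(sssi_resistant, path("sssi_resistant_fragments.bed"))

  ## array readout
  grid <- make_probe_grid(model, probe_spacing, probe_footprint)
  grid <- simulate_signals(grid, resistant, config$noise_sd,
                           seed = child_seed(config$seed, 7))
  grid <- normalize_probes(grid)
  write_probe_tsv(grid, path("probes.tsv"))
  write_bedgraph(data.frame(chrom = grid$chrom, start = grid$start,
                            end = grid$end, value = grid$log2_ratio),
                 path("log2_ratio.bedgraph"))

  ## domain calling
  calls <- classify_probes(grid)
  domains <- segment_domains(calls, grid)
  write_bed(data.frame(chrom = domains$chrom, start = domains$start,
                       end = domains$end, name = domains$label,
                       score = round(100 * domains$mean_fold_change)),
            path("domains.bed"))
  write_tsv_report(summarize_chromosomes(calls, grid),
                   path("chromosome_summary.tsv"))
  recovery <- compare_to_truth(domains, model$truth_domains)

  ## density tracks + correlations
  cpg_track <- cpg_density_track(model)
  write_bedgraph(cpg_track, path("cpg_density.bedgraph"))
  write_bedgraph(gene_density_track(model$genes, model),
                 path("gene_density.bedgraph"))
  cors <- list(
    h3k9ac_expression = mark_expression_correlation(
      model$genes, mark_track(model$marks, "h3k9ac")),
    h3k27me3_expression = mark_expression_correlation(
      model$genes, mark_track(model$marks, "h3k27me3")))
  cor_df <- data.frame(pair = names(cors),
                       r = vapply(cors, `[[`, numeric(1), "r"),
                       p = vapply(cors, `[[`, numeric(1), "p"),
                       n = vapply(cors, `[[`, numeric(1), "n"))
  write_tsv_report(cor_df, path("correlations.tsv"))
  write_tsv_report(classify_gene_patterns(model), path("gene_patterns.tsv"))

  ## bisulfite validation of the first truth HYPO domain
  bis <- NULL
  hypo <- td[td$label == "HYPO", , drop = FALSE]
  if (nrow(hypo) > 0) {
    h <- hypo[1, ]
    reg_end <- min(h$end, h$start + 200000L)  # cap for run time
    reads <- simulate_bisreads(model, h$chrom, h$start, reg_end,
                               coverage = bis_coverage,
                               seed = child_seed(config$seed, 11))
    x <- model$cpg[[h$chrom]]
    sites <- x$pos[x$pos >= h$start & x$pos < reg_end - 1L]
    bcalls <- call_methylation(reads, sites)
    write_tsv_report(bcalls, path("bisulfite_calls.tsv"))
    ok <- !is.na(bcalls$meth_fraction)
    write_bedgraph(data.frame(chrom = bcalls$chrom[ok],
                              start = bcalls$pos[ok],
                              end = bcalls$pos[ok] + 2L,
                              value = bcalls$meth_fraction[ok]),
                   path("bisulfite_meth.bedgraph"))
    bis <- bis_validate_domains(bcalls, td)
    jsonlite::write_json(bis, path("bisulfite_validation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## optional differential stage
  diff_out <- NULL
  if (!is.null(treat_domain)) {
    treated_model <- remethylate_domain(model, treat_domain)
    t_resistant <- size_select(mcrbc_digest(treated_model, params),
                               params$size_threshold)
    t_grid <- make_probe_grid(treated_model, probe_spacing, probe_footprint)
    t_grid <- simulate_signals(t_grid, t_resistant, config$noise_sd,
                               seed = child_seed(config$seed, 13))
    t_grid <- normalize_probes(t_grid)
    dtrack <- smooth_track(ratio_of_ratios(grid, t_grid))
    write_bedgraph(data.frame(chrom = dtrack$chrom, start = dtrack$start,
                              end = dtrack$end,
                              value = dtrack$ratio_of_ratios),
                   path("ratio_of_ratios.bedgraph"))
    write_bedgraph(data.frame(chrom = dtrack$chrom, start = dtrack$start,
                              end = dtrack$end, value = dtrack$smoothed),
                   path("ratio_of_ratios_smoothed.bedgraph"))
    enbloc <- detect_enbloc(dtrack, hypo, delta = enbloc_delta)
    write_tsv_report(enbloc, path("enbloc_changes.tsv"))
    sites <- differential_sites(calls, classify_probes(t_grid), grid)
    write_tsv_report(annotate_sites(sites, model$genes),
                     path("differential_sites.tsv"))
    diff_out <- list(track = dtrack, enbloc = enbloc, sites = sites)
  }

  manifest <- list(
    tool = "mcrbcarray", version = as.character(packageVersion("mcrbcarray")),
    seed = config$seed, config = unclass(config),
    params = unclass(params),
    probe_spacing = probe_spacing, probe_footprint = probe_footprint,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE))))
  write_manifest(manifest, path("manifest.json"))

  invisible(list(manifest = manifest, model = model, grid = grid,
                 calls = calls, domains = domains, recovery = recovery,
                 correlations = cors, bisulfite = bis,
                 differential = diff_out))
}

## atomic manifest write: temp file then rename
write_manifest <- function(manifest, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Re-methylate one truth HYPO domain (in-silico treatment)
#'
#' Returns a copy of the model in which the CpGs of the `index`-th truth
#' HYPO domain are redrawn at the background methylation probability —
#' the abstract representation of a treatment that re-methylates a domain
#' en bloc.
#'
#' @param model a `genome_model`.
#' @param index which truth HYPO domain (1-based).
#' @param seed RNG seed for the redraw.
#' @return a modified `genome_model`.
#' @export
remethylate_domain <- function(model, index = 1L, seed = NULL) {
  hypo <- model$truth_domains[model$truth_domains$label == "HYPO", ,
                              drop = FALSE]
  if (index < 1 || index > nrow(hypo))
    stopf("remethylate_domain: no truth HYPO domain #%d", index)
  h <- hypo[index, ]
  x <- model$cpg[[h$chrom]]
  sel <- x$pos >= h$start & x$pos < h$end
  with_seed(seed %||% child_seed(model$config$seed, 17), {
    x$meth[sel] <- as.numeric(rbinom(sum(sel), 1L,
                                     model$config$background_meth))
  })
  model$cpg[[h$chrom]] <- x
  model
}
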