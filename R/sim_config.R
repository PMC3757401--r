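#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_genome()]. Defaults
#' describe the desk-scale world the test-suite operates in: a 10 Mb
#' chromosome carrying a handful of megabase-scale hypomethylated domains
#' sitting in CpG-poor, gene-poor tracts, a heavily methylated background
#' (85% of CpGs), nearly unmethylated domains (5%), and an array readout
#' with 20% multiplicative lognormal noise.
#'
#' @param genome_length chromosome length in bp.
#' @param n_chromosomes number of chromosomes (all of `genome_length`).
#' @param gc_content background GC fraction (human-like default 0.41).
#' @param cpg_rate_high expected CpGs per bp outside hypomethylated domains.
#' @param cpg_rate_low expected CpGs per bp inside hypomethylated domains
#'   (CpG-poor gene deserts).
#' @param n_hypo_domains number of hypomethylated domains per chromosome.
#' @param hypo_domain_length length-2 numeric, min/max domain length in bp.
#' @param background_meth per-CpG methylation probability in the background.
#' @param domain_meth per-CpG methylation probability inside hypo domains.
#' @param n_genes genes per chromosome.
#' @param expression_coupling named length-2 numeric `c(h3k9ac=, h3k27me3=)`:
#'   effect sizes on log-expression; the first must be positive (activating
#'   mark), the second negative (repressive Polycomb mark).
#' @param noise_sd sd of the log of the multiplicative array-signal noise.
#' @param seed RNG seed; identical configs reproduce identical genomes.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e7,
                       n_chromosomes = 1,
                       gc_content = 0.41,
                       cpg_rate_high = 0.01,
                       cpg_rate_low = 0.001,
                       n_hypo_domains = 3,
                       hypo_domain_length = c(5e5, 1e6),
                       background_meth = 0.85,
                       domain_meth = 0.05,
                       n_genes = 500,
                       expression_coupling = c(h3k9ac = 2, h3k27me3 = -2),
                       noise_sd = 0.2,
                       seed = 1L) {
  cfg <- structure(list(
    genome_length = genome_length, n_chromosomes = n_chromosomes,
    gc_content = gc_content, cpg_rate_high = cpg_rate_high,
    cpg_rate_low = cpg_rate_low, n_hypo_domains = n_hypo_domains,
    hypo_domain_length = as.numeric(hypo_domain_length),
    background_meth = background_meth, domain_meth = domain_meth,
    n_genes = n_genes,
    expression_coupling = setNames(as.numeric(expression_coupling),
                                   c("h3k9ac", "h3k27me3")),
    noise_sd = noise_sd, seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$genome_length) || cfg$genome_length < 1)
    stopf("invalid sim_config: genome_length must be a positive integer")
  if (!is_count(cfg$n_chromosomes) || cfg$n_chromosomes < 1)
    stopf("invalid sim_config: n_chromosomes must be a positive integer")
  if (!is_prob(cfg$gc_content) || length(cfg$gc_content) != 1)
    stopf("invalid sim_config: gc_content must be a fraction in [0,1]")
  for (f in c("cpg_rate_high", "cpg_rate_low")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 0.5)
      stopf("invalid sim_config: %s must be in [0, 0.5] CpGs/bp", f)
  }
  if (!is_count(cfg$n_hypo_domains))
    stopf("invalid sim_config: n_hypo_domains must be a non-negative integer")
  hdl <- cfg$hypo_domain_length
  if (length(hdl) != 2 || any(!is.finite(hdl)) || hdl[1] < 1 ||
      hdl[2] < hdl[1])
    stopf("invalid sim_config: hypo_domain_length must be c(min, max), min >= 1")
  if (hdl[2] > cfg$genome_length)
    stopf("invalid sim_config: hypo_domain_length max exceeds genome_length")
  for (f in c("background_meth", "domain_meth")) {
    if (!is_prob(cfg[[f]]) || length(cfg[[f]]) != 1)
      stopf("invalid sim_config: %s must be a probability in [0,1]", f)
  }
  if (!is_count(cfg$n_genes))
    stopf("invalid sim_config: n_genes must be a non-negative integer")
  ec <- cfg$expression_coupling
  if (length(ec) != 2 || any(!is.finite(ec)) || ec[1] < 0 || ec[2] > 0)
    stopf(paste("invalid sim_config: expression_coupling must be",
                "c(h3k9ac >= 0, h3k27me3 <= 0)"))
  if (!is.numeric(cfg$noise_sd) || length(cfg$noise_sd) != 1 ||
      !is.finite(cfg$noise_sd) || cfg$noise_sd < 0)
    stopf("invalid sim_config: noise_sd must be a non-negative real")
  if (!is_count(abs(cfg$seed)))
    stopf("invalid sim_config: seed must be an integer")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' Every [sim_config()] field is addressable; missing fields fall back to the
#' documented defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stopf("unknown sim_config field(s) in %s: %s", path,
          paste(bad, collapse = ", "))
  vals$hypo_domain_length <- unlist(vals$hypo_domain_length)
  if (!is.null(vals$expression_coupling))
    vals$expression_coupling <- unlist(vals$expression_coupling)
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chromosomes, "chromosome(s) x",
      format(x$genome_length, big.mark = ","), "bp;",
      x$n_hypo_domains, "hypo domain(s); seed", x$seed, "\n")
  invisible(x)
}
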