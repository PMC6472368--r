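# Seeded generators for every input the pipeline consumes, with known
# ground truth. All generators are pure functions of (parameters, seed).
# One global seed fans out to fixed per-generator streams so adding a
# generator never perturbs existing outputs.

# Deterministic sub-seed for a named generator stream; result < 2^31.
fan_seed <- function(seed, stream) {
  streams <- c(genome_hits = 11L, gas_profiles = 23L, metabolites = 37L,
               asv_counts = 53L)
  if (!stream %in% names(streams)) {
    abort(sprintf("unknown generator stream '%s'", stream))
  }
  ((as.numeric(seed) %% 2147483647) * 69621 + streams[[stream]]) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic genome annotation hit tables with planted pathway truth
#'
#' Emulates per-genome annotation hit tables. For each genome, each pathway
#' in the catalog is planted with a random number of distinct gene
#' families: pathways intended *present* get at least their rule's
#' threshold, pathways intended *absent* get fewer (possibly zero,
#' including the threshold-minus-one boundary). Planted hits always pass
#' their database's cutoffs; spurious hits are drawn to *fail* them by at
#' least an order of magnitude in e-value (or well below the identity
#' cutoff), so recovery of the planted truth is exact by construction.
#'
#' @param n_genomes Number of genomes.
#' @param rules A `seep_ruleset` supplying the pathway catalog, family
#'   memberships and cutoffs.
#' @param spurious_rate Expected number of sub-threshold spurious hits per
#'   genome per pathway, in `[0, 1]` scaled by family count (0 = none).
#' @param p_present Probability a genome carries a given pathway.
#' @param seed Integer seed (fanned to the generator's own stream).
#' @param database_tag Database whose cutoffs planted hits must pass.
#' @return A list: `hits` (a hit tibble) and `truth` (tibble `genome_id`,
#'   `pathway`, `n_families`, `present` — presence under the ruleset).
#' @examples
#' syn <- gen_genome_hits(3, seed = 1)
#' head(syn$truth)
#' @export
gen_genome_hits <- function(n_genomes, rules = default_ruleset(),
                            spurious_rate = 0, p_present = 0.5, seed = 1,
                            database_tag = "custom") {
  if (spurious_rate < 0 || spurious_rate > 1) {
    abort("spurious_rate must lie in [0, 1]")
  }
  if (!database_tag %in% rules$cutoffs$database_tag) {
    abort(sprintf("unknown database_tag '%s'", database_tag))
  }
  cut <- rules$cutoffs[rules$cutoffs$database_tag == database_tag, ]
  fam <- rules$families
  pathways <- unique(fam$pathway)
  min_genes <- setNames(rep(1L, length(pathways)), pathways)
  rule_idx <- match(rules$pathway_rules$pathway, pathways)
  min_genes[rule_idx[!is.na(rule_idx)]] <-
    rules$pathway_rules$min_genes[!is.na(rule_idx)]

  with_seed(fan_seed(seed, "genome_hits"), {
    genomes <- sprintf("genome_%02d", seq_len(n_genomes))
    plan <- tidyr::expand_grid(genome_id = genomes, pathway = pathways) %>%
      mutate(available = vapply(.data$pathway,
                                function(p) sum(fam$pathway == p), integer(1),
                                USE.NAMES = FALSE),
             threshold = unname(min_genes[.data$pathway]),
             intend = stats::runif(dplyr::n()) < p_present)
    # intended-present: n in [threshold, available]; absent: n in [0, threshold-1]
    pick <- function(lo, hi) if (lo >= hi) as.integer(lo) else
      as.integer(sample(seq.int(lo, hi), 1))
    plan$n_families <- purrr::pmap_int(
      plan[c("available", "threshold", "intend")],
      function(available, threshold, intend) {
        if (intend) pick(threshold, available) else pick(0L, threshold - 1L)
      })
    hits <- purrr::pmap_dfr(
      plan[c("genome_id", "pathway", "n_families")],
      function(genome_id, pathway, n_families) {
        if (n_families == 0) return(NULL)
        fams <- sample(fam$family_id[fam$pathway == pathway], n_families)
        tibble(genome_id = genome_id,
               gene_id = paste0(genome_id, "_", pathway, "_", seq_along(fams)),
               family_id = fams,
               pathway_label = pathway,
               evalue = passing_evalue(length(fams), cut),
               identity_pct = passing_identity(length(fams), cut),
               coverage_frac = passing_coverage(length(fams), cut),
               bitscore = round(stats::runif(length(fams), 80, 500), 1),
               database_tag = cut$database_tag)
      })
    if (spurious_rate > 0) {
      spur <- purrr::pmap_dfr(
        plan[c("genome_id", "pathway")],
        function(genome_id, pathway) {
          n_spur <- stats::rbinom(1, sum(fam$pathway == pathway), spurious_rate)
          if (n_spur == 0) return(NULL)
          fams <- sample(fam$family_id[fam$pathway == pathway], n_spur)
          tibble(genome_id = genome_id,
                 gene_id = paste0(genome_id, "_spur_", pathway, "_", seq_along(fams)),
                 family_id = fams,
                 pathway_label = pathway,
                 evalue = failing_evalue(length(fams), cut),
                 identity_pct = failing_identity(length(fams), cut),
                 coverage_frac = failing_coverage(length(fams), cut),
                 bitscore = round(stats::runif(length(fams), 20, 60), 1),
                 database_tag = cut$database_tag)
        })
      hits <- bind_rows(hits, spur)
    }
    truth <- plan %>%
      mutate(present = .data$n_families >= .data$threshold) %>%
      select("genome_id", "pathway", "n_families", "present")
    list(hits = as_tibble(hits), truth = truth)
  })
}

# Hit-score fields that pass (or fail by a wide margin) the cutoffs.
passing_evalue <- function(n, cut) {
  e_max <- if (is.na(cut$max_evalue)) 1e-5 else cut$max_evalue
  e_max * 10^(-stats::runif(n, 0, 20))
}
failing_evalue <- function(n, cut) {
  e_max <- if (is.na(cut$max_evalue)) 1e-5 else cut$max_evalue
  pmin(e_max * 10^(stats::runif(n, 1, 6)), 10)  # >= 10x above the cutoff
}
passing_identity <- function(n, cut) {
  lo <- if (is.na(cut$min_identity_pct)) 30 else cut$min_identity_pct
  stats::runif(n, lo, 100)
}
failing_identity <- function(n, cut) {
  hi <- if (is.na(cut$min_identity_pct)) 25 else max(cut$min_identity_pct - 5, 1)
  stats::runif(n, 0, hi)
}
passing_coverage <- function(n, cut) {
  lo <- if (is.na(cut$min_coverage_frac)) 0.5 else cut$min_coverage_frac
  stats::runif(n, lo, 1)
}
failing_coverage <- function(n, cut) {
  hi <- if (is.na(cut$min_coverage_frac)) 0.3 else max(cut$min_coverage_frac - 0.1, 0.01)
  stats::runif(n, 0, hi)
}

#' Synthetic gas geochemistry profiles with planted origin regimes
#'
#' Draws site gas profiles from planted regimes. Biogenic sites get a
#' Bernard ratio strictly above 1000 and methane delta13C below -60
#' permil; thermogenic sites a ratio below 100 and delta13C above -50;
#' `mixed` sites get deliberately conflicting evidence (biogenic ratio,
#' thermogenic isotope). Classifier recovery is therefore exact on the
#' non-mixed regimes.
#'
#' @param n_sites Number of sites.
#' @param regimes Character vector recycled over sites, entries in
#'   `c("biogenic", "thermogenic", "mixed")`.
#' @param seed Integer seed.
#' @return A list: `profiles` (tibble `site_id`, `total_alkane_gas_ppm`,
#'   `c2plus_ppm`, `c1_ppm`, `c2_ppm`, `c3_ppm`, `c1_c2c3_ratio`,
#'   `d13C_CH4_permil`) and `truth` (tibble `site_id`, `regime`).
#' @examples
#' gen_gas_profiles(4, c("biogenic", "thermogenic"), seed = 7)$truth
#' @export
gen_gas_profiles <- function(n_sites, regimes = "biogenic", seed = 1) {
  if (n_sites == 0) {
    empty <- tibble(site_id = character(), total_alkane_gas_ppm = numeric(),
                    c2plus_ppm = numeric(), c1_ppm = numeric(),
                    c2_ppm = numeric(), c3_ppm = numeric(),
                    c1_c2c3_ratio = numeric(), d13C_CH4_permil = numeric())
    return(list(profiles = empty,
                truth = tibble(site_id = character(), regime = character())))
  }
  regimes <- rep_len(regimes, n_sites)
  bad <- setdiff(unique(regimes), c("biogenic", "thermogenic", "mixed"))
  if (length(bad) > 0) {
    abort(sprintf("unknown regime(s): %s", paste(bad, collapse = ", ")))
  }
  with_seed(fan_seed(seed, "gas_profiles"), {
    draw <- function(regime) {
      switch(regime,
        biogenic = list(ratio = 10^stats::runif(1, 3.05, 4.5),
                        d13C = stats::runif(1, -95, -65)),
        thermogenic = list(ratio = 10^stats::runif(1, 0.3, 1.9),
                           d13C = stats::runif(1, -45, -30)),
        mixed = list(ratio = 10^stats::runif(1, 3.05, 4.5),
                     d13C = stats::runif(1, -45, -30)))
    }
    rows <- purrr::imap_dfr(regimes, function(regime, i) {
      d <- draw(regime)
      c1 <- 10^stats::runif(1, 4.5, 6)
      c2c3 <- c1 / d$ratio
      c2 <- c2c3 * stats::runif(1, 0.55, 0.85)
      tibble(site_id = sprintf("site_%02d", i),
             c1_ppm = c1, c2_ppm = c2, c3_ppm = c2c3 - c2,
             c2plus_ppm = c2c3 * stats::runif(1, 1.0, 1.3),
             c1_c2c3_ratio = d$ratio, d13C_CH4_permil = d$d13C)
    })
    profiles <- rows %>%
      mutate(total_alkane_gas_ppm = .data$c1_ppm + .data$c2plus_ppm) %>%
      select("site_id", "total_alkane_gas_ppm", "c2plus_ppm", "c1_ppm",
             "c2_ppm", "c3_ppm", "c1_c2c3_ratio", "d13C_CH4_permil")
    list(profiles = profiles,
         truth = tibble(site_id = profiles$site_id, regime = regimes))
  })
}

#' Synthetic metabolite intensity matrices with planted compound means
#'
#' Emulates a technical-replicate metabolomics design (default 5
#' replicates per site): each compound gets a planted mean fractional
#' abundance per site (log-normal across compounds), and replicate
#' intensities are drawn log-normally around the planted means with the
#' requested coefficient of variation. At `cv = 0` replicates are
#' identical.
#'
#' @param n_compounds,n_sites,replicates Design dimensions.
#' @param cv Technical coefficient of variation of replicate intensities
#'   (>= 0).
#' @param seed Integer seed.
#' @return A list: `table` (wide tibble `compound` x sample columns),
#'   `sample_map` (tibble `sample`, `site`, `replicate`), `pathway_map`
#'   (tibble `compound`, `pathway`, `dual_pathway_flag`) and `truth`
#'   (tibble `site`, `compound`, `planted_fraction`).
#' @examples
#' syn <- gen_metabolite_matrix(10, 2, replicates = 5, cv = 0.1, seed = 3)
#' dim(syn$table)
#' @export
gen_metabolite_matrix <- function(n_compounds, n_sites, replicates = 5,
                                  cv = 0.1, seed = 1) {
  if (cv < 0) abort("cv must be >= 0")
  if (replicates < 1) abort("replicates must be >= 1")
  with_seed(fan_seed(seed, "metabolites"), {
    compounds <- sprintf("compound_%03d", seq_len(n_compounds))
    pathways <- c("carbohydrate", "amino_acid", "beta_oxidation",
                  "aromatic_degradation", "fumarate_addition")
    pathway_map <- tibble(
      compound = compounds,
      pathway = sample(pathways, n_compounds, replace = TRUE),
      dual_pathway_flag = stats::runif(n_compounds) < 0.1)
    sdlog <- sqrt(log(1 + cv^2))
    sites <- sprintf("site_%02d", seq_len(n_sites))
    truth <- purrr::map_dfr(sites, function(site) {
      base <- stats::rlnorm(n_compounds, meanlog = 0, sdlog = 1.5)
      tibble(site = site, compound = compounds,
             planted_fraction = base / sum(base))
    })
    table <- tibble(compound = compounds)
    sample_map <- tidyr::expand_grid(site = sites,
                                     replicate = seq_len(replicates)) %>%
      mutate(sample = sprintf("%s_rep%d", .data$site, .data$replicate)) %>%
      select("sample", "site", "replicate")
    for (i in seq_len(nrow(sample_map))) {
      mu <- truth$planted_fraction[truth$site == sample_map$site[i]]
      noise <- if (cv == 0) rep(1, n_compounds) else
        stats::rlnorm(n_compounds, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      table[[sample_map$sample[i]]] <- mu * 1e8 * noise
    }
    list(table = table, sample_map = sample_map,
         pathway_map = pathway_map, truth = truth)
  })
}

#' Synthetic ASV count vectors with known true richness
#'
#' Multinomial sample of sequencing `depth` reads from a long-tailed
#' community of `s_true` taxa under a geometric or log-series rank
#' abundance model — the shape of amplicon libraries on which Chao1 is
#' used. Shallow depths leave rare taxa unobserved, so `S_obs < s_true`
#' while the Chao1 estimate moves back toward `s_true`.
#'
#' @param s_true True taxon richness (>= 1).
#' @param depth Total reads drawn (>= 1).
#' @param model `"geometric"` (rank decay `k^(rank-1)`) or `"logseries"`.
#' @param decay Geometric decay parameter in (0, 1) (ignored for
#'   log-series).
#' @param seed Integer seed.
#' @return A list: `counts` (tibble `taxon`, `count`, zero rows dropped)
#'   and `truth` (list with `s_true`, `model`, `depth`).
#' @examples
#' gen_asv_counts(50, depth = 200, seed = 5)$truth$s_true
#' @export
gen_asv_counts <- function(s_true, depth, model = c("geometric", "logseries"),
                           decay = 0.93, seed = 1) {
  model <- match.arg(model)
  if (s_true < 1) abort("s_true must be >= 1")
  if (depth < 1) abort("depth must be >= 1")
  p <- switch(model,
    geometric = decay^(seq_len(s_true) - 1),
    logseries = {
      theta <- 0.95
      theta^seq_len(s_true) / seq_len(s_true)
    })
  p <- p / sum(p)
  with_seed(fan_seed(seed, "asv_counts"), {
    x <- as.integer(stats::rmultinom(1, size = depth, prob = p)[, 1])
    counts <- tibble(taxon = sprintf("asv_%04d", seq_len(s_true)),
                     count = x) %>%
      filter(.data$count > 0)
    list(counts = counts,
         truth = list(s_true = s_true, model = model, depth = depth))
  })
}

#' Generate a complete synthetic study
#'
#' Fans a single seed out to every generator and (optionally) writes the
#' full fixture directory a pipeline run consumes: `hits.tsv`, `gas.tsv`,
#' `metabolites.csv`, `metabolite_samples.csv`, `metabolite_pathways.csv`,
#' `asv_counts.tsv` and `truth.json`. Regenerating with the same seed and
#' sizes reproduces every file byte-identically.
#'
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and just returns the objects.
#' @param seed Global seed.
#' @param n_genomes,n_sites,n_compounds,replicates,s_true,depth Sizes.
#' @param spurious_rate,cv Noise levels (defaults: none).
#' @param regimes Gas regimes recycled over sites.
#' @return Invisibly, a named list of all generated objects.
#' @export
synthetic_study <- function(out_dir = NULL, seed = 1, n_genomes = 8,
                            n_sites = 3, n_compounds = 40, replicates = 5,
                            s_true = 400, depth = 5000, spurious_rate = 0,
                            cv = 0.1,
                            regimes = c("biogenic", "thermogenic")) {
  rules <- default_ruleset()
  genome <- gen_genome_hits(n_genomes, rules, spurious_rate = spurious_rate,
                            seed = seed)
  gas <- gen_gas_profiles(n_sites, regimes, seed = seed)
  metab <- gen_metabolite_matrix(n_compounds, n_sites, replicates, cv = cv,
                                 seed = seed)
  asv <- gen_asv_counts(s_true, depth, seed = seed)
  out <- list(hits = genome$hits, genome_truth = genome$truth,
              gas = gas$profiles, gas_truth = gas$truth,
              metabolites = metab$table, sample_map = metab$sample_map,
              pathway_map = metab$pathway_map, metabolite_truth = metab$truth,
              asv_counts = asv$counts, asv_truth = asv$truth,
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(genome$hits, file.path(out_dir, "hits.tsv"))
    readr::write_tsv(gas$profiles, file.path(out_dir, "gas.tsv"))
    readr::write_csv(metab$table, file.path(out_dir, "metabolites.csv"))
    readr::write_csv(metab$sample_map, file.path(out_dir, "metabolite_samples.csv"))
    readr::write_csv(metab$pathway_map, file.path(out_dir, "metabolite_pathways.csv"))
    readr::write_tsv(asv$counts, file.path(out_dir, "asv_counts.tsv"))
    truth <- list(seed = seed,
                  genome = genome$truth, gas = gas$truth,
                  metabolites = metab$truth, asv = asv$truth)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
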