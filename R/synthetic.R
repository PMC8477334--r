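# Synthetic cohort generator. Emulates the structure of a lung-cancer
# screening cohort: ~50 patients biopsied at several anatomic locations
# over yearly bronchoscopies, plus mainstem-bronchus brushes, with highly
# variable TCR read depth, a shared public clone pool and patient-private
# pools, within-patient clone re-use strongest at shared timepoints,
# planted clonal expansions (some recurring at the same location at the
# next timepoint), and a lesion outcome that lowers the diversity of
# regressive lesions. Ground truth for every planted effect is returned so
# the downstream callers can be validated.

.ANTIGENS <- data.frame(
  antigen = c("pp65", "IE1", "BMLF1", "LMP2", "M1", "NS4B", "NS3",
              "Gag", "MART-1", "BST2"),
  species = c("CMV", "CMV", "EBV", "EBV", "InfluenzaA", "YellowFeverVirus",
              "HCV", "HIV-1", "HomoSapiens", "HomoSapiens"),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the screening-cohort scenario the analysis was designed
#' for: 50 patients, 3 yearly bronchoscopies with biopsies at 2 anatomic
#' locations plus a mainstem brush each, log-normal TCR read depth with
#' roughly a quarter of samples above the 250-read expansion filter, a
#' shared public clone pool and disjoint patient-private pools, and
#' within-patient clone re-use weighted so that sharing is strongest
#' between same-timepoint samples, then same-location samples.
#'
#' @param n_patients Number of patients.
#' @param timepoints_per_patient Bronchoscopy procedures per patient.
#' @param locations_per_patient Biopsied anatomic locations per patient.
#' @param brushes_per_patient Mainstem brushes per patient (at most one per
#'   timepoint).
#' @param depth_log_mean,depth_log_sd Natural-log mean and SD of the
#'   per-sample TCR read depth (log-normal).
#' @param active_rate Expected distinct active clones per TCR read; sets
#'   the diversity scale (CPK is about `1000 * active_rate` before
#'   multinomial dropout).
#' @param public_pool_size,private_pool_size Clones in the cohort-shared
#'   public pool and in each patient-private pool (pools are disjoint).
#' @param p_public_draw Probability an active clone is drawn from the
#'   public pool.
#' @param within_patient_overlap_boost Multiplicative sampling weight for a
#'   clone the patient has used in any earlier sample.
#' @param same_time_boost,same_location_boost Additional multiplicative
#'   weights when the clone was already used at the same timepoint /
#'   anatomic location of that patient; `same_time_boost >=
#'   same_location_boost >= 1` reproduces the observed ordering of sharing.
#' @param dirichlet_concentration Per-clone Dirichlet concentration of
#'   within-sample clone abundances (small values give realistic
#'   overdispersion).
#' @param n_planted_expanded Number of planted expanded (sample, clone)
#'   pairs.
#' @param expansion_fold Multiplier on a planted clone's abundance weight.
#' @param p_recurrent_expansion Probability a planted expansion is planted
#'   again at the same location at the next timepoint.
#' @param public_expansion_bias Probability a planted expansion uses a
#'   public-pool clone (set above `p_public_draw` so expanded clones are
#'   enriched for public ones).
#' @param planted_min_reads Expansions are planted only in biopsies with at
#'   least this many reads, so recovery is well defined after the read
#'   filter.
#' @param outcome_effect Multiplier on the active-clone count of samples
#'   from regressive lesions (< 1 lowers their CPK).
#' @param p_proliferative Probability a lesion is of the proliferative
#'   molecular subtype.
#' @param p_regressive Probability a lesion's outcome is regressive (else
#'   progressive/persistent).
#' @param module_score_noise_sd Noise SD on the per-sample immune module
#'   score (which is built to be negatively coupled to CPK).
#' @param module_gene_noise_sd Per-gene expression noise around the module
#'   score.
#' @param n_module_genes,n_decoy_genes Genes in the immune module / decoy
#'   genes in the emitted expression matrix.
#' @param db_rate_public,db_rate_private Probability that a public-pool /
#'   private clone carries an antigen-specificity database annotation.
#' @param chain_probs Sampling probabilities of chains TRA, TRB, TRG, TRD
#'   for pool clones.
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   configuration.
#' @return A list of class `tcr_synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 50,
                             timepoints_per_patient = 3,
                             locations_per_patient = 2,
                             brushes_per_patient = 3,
                             depth_log_mean = 4.7,
                             depth_log_sd = 1.2,
                             active_rate = 0.04,
                             public_pool_size = 600,
                             private_pool_size = 300,
                             p_public_draw = 0.25,
                             within_patient_overlap_boost = 10,
                             same_time_boost = 6,
                             same_location_boost = 3,
                             dirichlet_concentration = 0.8,
                             n_planted_expanded = 40,
                             expansion_fold = 50,
                             p_recurrent_expansion = 0.6,
                             public_expansion_bias = 0.45,
                             planted_min_reads = 250,
                             outcome_effect = 0.8,
                             p_proliferative = 0.35,
                             p_regressive = 0.55,
                             module_score_noise_sd = 0.5,
                             module_gene_noise_sd = 0.4,
                             n_module_genes = 25,
                             n_decoy_genes = 50,
                             db_rate_public = 0.087,
                             db_rate_private = 0.015,
                             chain_probs = c(TRA = 0.35, TRB = 0.55,
                                             TRG = 0.05, TRD = 0.05),
                             seed = 17) {
  cfg <- as.list(environment())
  class(cfg) <- "tcr_synthetic_config"
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  probs <- c(cfg$p_public_draw, cfg$p_recurrent_expansion,
             cfg$public_expansion_bias, cfg$p_proliferative,
             cfg$p_regressive, cfg$db_rate_public, cfg$db_rate_private)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  boosts <- c(cfg$within_patient_overlap_boost, cfg$same_time_boost,
              cfg$same_location_boost)
  if (any(boosts < 1)) stop("boosts must be >= 1")
  if (cfg$same_time_boost < cfg$same_location_boost) {
    stop("same_time_boost must be >= same_location_boost")
  }
  counts <- c(cfg$n_patients, cfg$timepoints_per_patient,
              cfg$locations_per_patient, cfg$public_pool_size,
              cfg$private_pool_size)
  if (any(counts < 1)) stop("cohort dimensions and pool sizes must be >= 1")
  if (cfg$brushes_per_patient > cfg$timepoints_per_patient) {
    stop("at most one brush per timepoint")
  }
  if (cfg$expansion_fold < 1) stop("expansion_fold must be >= 1")
  if (cfg$active_rate <= 0 || cfg$dirichlet_concentration <= 0) {
    stop("active_rate and dirichlet_concentration must be positive")
  }
  invisible(cfg)
}

# Random CDR3 amino-acid strings, unique, lengths 8-20, C...F framing like
# real junctions.
.random_cdr3 <- function(n) {
  aa <- strsplit(.AA_ALPHABET, "")[[1]]
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(8:20, need, replace = TRUE)
    cols <- lapply(1:18, function(i) sample(aa, need, replace = TRUE))
    body <- do.call(paste0, cols)
    cand <- paste0("C", substr(body, 1, lens - 2), "F")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

# Clone pools: one shared public pool plus a disjoint private pool per
# patient. Deterministic given the config seed.
.make_pools_raw <- function(cfg) {
  n_total <- cfg$public_pool_size + cfg$n_patients * cfg$private_pool_size
  cdr3 <- .random_cdr3(n_total)
  chain <- sample(names(cfg$chain_probs), n_total, replace = TRUE,
                  prob = cfg$chain_probs)
  origin <- c(rep("public", cfg$public_pool_size),
              rep(sprintf("P%02d", seq_len(cfg$n_patients)),
                  each = cfg$private_pool_size))
  data.frame(clone_id = seq_len(n_total), cdr3_aa = cdr3, chain = chain,
             origin = origin, stringsAsFactors = FALSE)
}

.make_pools <- function(cfg) {
  withr::with_seed(cfg$seed, .make_pools_raw(cfg))
}

#' Generate a synthetic cohort with ground truth
#'
#' Depths are drawn from the configured log-normal; each sample's active
#' clone set is drawn from the public and patient-private pools with
#' multiplicative re-use weights (within-patient, same-timepoint,
#' same-location); within-sample abundances are Dirichlet-multinomial;
#' planted expansions multiply a clone's abundance weight by
#' `expansion_fold`; regressive lesions have their active-clone count
#' shrunk by `outcome_effect`; and the per-sample immune module score is
#' built as minus the standardised CPK plus noise, so the CPK-module
#' association is negative by construction.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `tcr_synthetic` with elements `cohort` (a
#'   `tcr_cohort` of biopsies and brushes), `truth` (lists `clonotypes`,
#'   `expansions`, `samples` carrying the planted ground truth),
#'   `expression` (genes x biopsy-samples matrix), `module_genes`, and
#'   `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  .validate_config(config)
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  pools <- .make_pools_raw(cfg)
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  locs <- sprintf("L%d", seq_len(cfg$locations_per_patient))

  ## sample frame -----------------------------------------------------------
  frames <- list()
  for (p in patients) {
    for (t in seq_len(cfg$timepoints_per_patient)) {
      frames[[length(frames) + 1L]] <- data.frame(
        patient_id = p, timepoint = t,
        location = locs, sample_type = "biopsy", stringsAsFactors = FALSE)
      if (t <= cfg$brushes_per_patient) {
        frames[[length(frames) + 1L]] <- data.frame(
          patient_id = p, timepoint = t,
          location = "MS", sample_type = "brush", stringsAsFactors = FALSE)
      }
    }
  }
  sm <- do.call(rbind, frames)
  sm$sample_id <- sprintf("%s_T%d_%s", sm$patient_id, sm$timepoint,
                          sm$location)
  sm$depth <- pmax(10L, as.integer(round(stats::rlnorm(
    nrow(sm), cfg$depth_log_mean, cfg$depth_log_sd))))

  ## lesion-level subtype and outcome ---------------------------------------
  lesion <- unique(sm[sm$sample_type == "biopsy", c("patient_id", "location")])
  lesion$subtype <- ifelse(
    stats::runif(nrow(lesion)) < cfg$p_proliferative, "proliferative",
    sample(c("inflammatory", "secretory", "normal-like"), nrow(lesion),
           replace = TRUE))
  lesion$outcome <- ifelse(stats::runif(nrow(lesion)) < cfg$p_regressive,
                           "regressive", "progressive/persistent")
  les_key <- paste(lesion$patient_id, lesion$location)
  idx <- match(paste(sm$patient_id, sm$location), les_key)
  sm$subtype <- ifelse(sm$sample_type == "biopsy", lesion$subtype[idx], "")
  sm$outcome <- ifelse(sm$sample_type == "biopsy", lesion$outcome[idx],
                       "unknown")

  ## planted expansions ------------------------------------------------------
  eligible <- which(sm$sample_type == "biopsy" &
                      sm$depth >= cfg$planted_min_reads)
  planted <- data.frame(sample_idx = integer(0), clone_id = integer(0),
                        recurrent = logical(0))
  if (cfg$n_planted_expanded > 0) {
    if (length(eligible) == 0) {
      stop("infeasible config: no biopsy reaches planted_min_reads, ",
           "cannot plant expansions")
    }
    pub_ids <- pools$clone_id[pools$origin == "public"]
    tries <- 0
    n_primary <- 0
    # one planted clone per sample, so each planted abundance is a
    # controlled expansion_fold multiple of a typical clone's
    while (n_primary < cfg$n_planted_expanded && tries < 10000) {
      tries <- tries + 1
      free <- setdiff(eligible, planted$sample_idx)
      if (length(free) == 0) break
      si <- free[sample.int(length(free), 1)]
      use_public <- stats::runif(1) < cfg$public_expansion_bias
      cl <- if (use_public) sample(pub_ids, 1) else {
        sample(pools$clone_id[pools$origin == sm$patient_id[si]], 1)
      }
      rec <- FALSE
      extra <- NULL
      if (stats::runif(1) < cfg$p_recurrent_expansion) {
        nxt <- which(sm$patient_id == sm$patient_id[si] &
                       sm$location == sm$location[si] &
                       sm$timepoint == sm$timepoint[si] + 1L)
        if (length(nxt) == 1 && sm$depth[nxt] >= cfg$planted_min_reads &&
            !nxt %in% planted$sample_idx && nxt != si) {
          rec <- TRUE
          extra <- data.frame(sample_idx = nxt, clone_id = cl,
                              recurrent = TRUE)
        }
      }
      planted <- rbind(planted,
                       data.frame(sample_idx = si, clone_id = cl,
                                  recurrent = rec),
                       extra)
      n_primary <- n_primary + 1
    }
    if (n_primary < cfg$n_planted_expanded) {
      stop("infeasible config: could not place ", cfg$n_planted_expanded,
           " planted expansions in samples passing planted_min_reads")
    }
  }
  planted_by_sample <- split(planted$clone_id, planted$sample_idx)

  ## per-sample clone draws --------------------------------------------------
  ord <- order(sm$patient_id, sm$timepoint, sm$sample_type, sm$location)
  pub_ids <- pools$clone_id[pools$origin == "public"]
  priv_ids <- split(pools$clone_id[pools$origin != "public"],
                    pools$origin[pools$origin != "public"])
  rec_sample <- vector("list", nrow(sm))

  state_used <- new.env(parent = emptyenv())      # per patient: clone ids used
  state_time <- new.env(parent = emptyenv())      # per patient_time
  state_loc <- new.env(parent = emptyenv())       # per patient_location

  # planted expanded clones behave as persistent clones of their patient:
  # they sit in the patient's re-use pool from the start, so they tend to
  # appear (at background abundance) in the patient's other samples too
  if (nrow(planted) > 0) {
    for (j in seq_len(nrow(planted))) {
      p <- sm$patient_id[planted$sample_idx[j]]
      state_used[[p]] <- union(state_used[[p]], planted$clone_id[j])
    }
  }

  boost_weights <- function(ids, p, t, loc) {
    w <- rep(1, length(ids))
    used <- state_used[[p]]
    if (!is.null(used)) {
      w <- w * ifelse(ids %in% used, cfg$within_patient_overlap_boost, 1)
      ut <- state_time[[paste0(p, "_", t)]]
      if (!is.null(ut)) w <- w * ifelse(ids %in% ut, cfg$same_time_boost, 1)
      ul <- state_loc[[paste0(p, "_", loc)]]
      if (!is.null(ul)) w <- w * ifelse(ids %in% ul, cfg$same_location_boost, 1)
    }
    w
  }

  for (i in ord) {
    p <- sm$patient_id[i]; t <- sm$timepoint[i]; loc <- sm$location[i]
    n_reads <- sm$depth[i]
    k <- max(2L, as.integer(round(cfg$active_rate * n_reads)))
    if (sm$sample_type[i] == "biopsy" && sm$outcome[i] == "regressive") {
      k <- max(2L, as.integer(round(k * cfg$outcome_effect)))
    }
    my_priv <- priv_ids[[p]]
    n_pub <- stats::rbinom(1, k, cfg$p_public_draw)
    n_pub <- min(n_pub, length(pub_ids))
    n_priv <- min(k - n_pub, length(my_priv))
    draw_pub <- if (n_pub > 0) {
      sample(pub_ids, n_pub, prob = boost_weights(pub_ids, p, t, loc))
    } else integer(0)
    draw_priv <- if (n_priv > 0) {
      sample(my_priv, n_priv, prob = boost_weights(my_priv, p, t, loc))
    } else integer(0)
    active <- c(draw_pub, draw_priv)

    forced <- planted_by_sample[[as.character(i)]]
    if (!is.null(forced)) active <- union(active, forced)

    w <- stats::rgamma(length(active), shape = cfg$dirichlet_concentration,
                       rate = 1)
    w <- pmax(w, 1e-12)
    if (!is.null(forced)) {
      # planted clones get expansion_fold times the mean clone weight,
      # independent of their own gamma draw, so the planted abundance is
      # a controlled multiple of a typical clone's
      w[active %in% forced] <- cfg$expansion_fold * cfg$dirichlet_concentration
    }
    counts <- as.integer(stats::rmultinom(1, n_reads, w / sum(w)))
    keep <- counts > 0
    rec_sample[[i]] <- data.frame(sample_idx = i, clone_id = active[keep],
                                  read_count = counts[keep])

    state_used[[p]] <- union(state_used[[p]], active[keep])
    kt <- paste0(p, "_", t); kl <- paste0(p, "_", loc)
    state_time[[kt]] <- union(state_time[[kt]], active[keep])
    state_loc[[kl]] <- union(state_loc[[kl]], active[keep])
  }

  raw <- do.call(rbind, rec_sample)
  records <- tibble::tibble(
    sample_id = sm$sample_id[raw$sample_idx],
    cdr3_aa = pools$cdr3_aa[raw$clone_id],
    cdr3_nt = NA_character_,
    chain = pools$chain[raw$clone_id],
    v_call = NA_character_,
    j_call = NA_character_,
    read_count = raw$read_count
  )
  metadata <- tibble::as_tibble(sm[c("sample_id", "patient_id", "location",
                                     "timepoint", "sample_type", "subtype",
                                     "outcome")])
  cohort <- build_cohort(records, metadata)

  ## module scores and expression matrix (biopsies) --------------------------
  bio <- cohort$totals[metadata$sample_type == "biopsy", , drop = FALSE]
  cpk <- bio$unique_clonotypes / bio$total_reads * 1000
  score <- as.numeric(-scale(cpk)) +
    stats::rnorm(length(cpk), 0, cfg$module_score_noise_sd)
  module_genes <- sprintf("IMM%03d", seq_len(cfg$n_module_genes))
  decoy_genes <- sprintf("GENE%03d", seq_len(cfg$n_decoy_genes))
  expr_mod <- t(vapply(module_genes, function(g) {
    score + stats::rnorm(length(score), 0, cfg$module_gene_noise_sd)
  }, numeric(length(score))))
  expr_dec <- matrix(stats::rnorm(cfg$n_decoy_genes * length(score)),
                     nrow = cfg$n_decoy_genes)
  expression <- rbind(expr_mod, expr_dec)
  rownames(expression) <- c(module_genes, decoy_genes)
  colnames(expression) <- bio$sample_id

  ## ground truth ------------------------------------------------------------
  used_clones <- sort(unique(raw$clone_id))
  truth_clono <- tibble::tibble(
    key = paste0(pools$chain[used_clones], ":", pools$cdr3_aa[used_clones]),
    chain = pools$chain[used_clones],
    cdr3_aa = pools$cdr3_aa[used_clones],
    origin = pools$origin[used_clones],
    pool_public = pools$origin[used_clones] == "public"
  )
  truth_exp <- tibble::tibble(
    sample_id = sm$sample_id[planted$sample_idx],
    key = paste0(pools$chain[planted$clone_id], ":",
                 pools$cdr3_aa[planted$clone_id]),
    recurrent = planted$recurrent
  )
  truth_samples <- tibble::tibble(
    sample_id = metadata$sample_id,
    outcome = metadata$outcome,
    true_module_score = NA_real_
  )
  truth_samples$true_module_score[match(bio$sample_id,
                                        truth_samples$sample_id)] <- score

  structure(
    list(cohort = cohort,
         truth = list(clonotypes = truth_clono, expansions = truth_exp,
                      samples = truth_samples),
         expression = expression,
         module_genes = module_genes,
         config = cfg),
    class = "tcr_synthetic"
  )
}

#' Generate a stand-in healthy-donor beta-CDR3 reference set
#'
#' Returns every beta-chain CDR3 of the public pool plus random decoys, as
#' a stand-in for a large external peripheral-blood reference (such as a
#' multi-hundred-donor healthy cohort). The public core is determined by
#' the configuration seed; the decoys by `decoy_seed`, so changing
#' `decoy_seed` replaces the decoys but not the core.
#'
#' @param config A [synthetic_config()].
#' @param n_subjects Nominal number of reference donors; the decoy count
#'   scales linearly with it.
#' @param decoy_seed Seed for the decoy draws (default `config$seed + 1`).
#' @return Character vector of beta CDR3 amino-acid sequences.
#' @export
generate_reference_set <- function(config, n_subjects = 666,
                                   decoy_seed = NULL) {
  .validate_config(config)
  stopifnot(n_subjects >= 1)
  if (is.null(decoy_seed)) decoy_seed <- config$seed + 1L
  pools <- .make_pools(config)
  core <- pools$cdr3_aa[pools$origin == "public" & pools$chain == "TRB"]
  decoys <- withr::with_seed(decoy_seed,
                             .random_cdr3(max(1L, round(n_subjects * 5))))
  unique(c(core, decoys))
}

#' Generate stand-in antigen-specificity database tables
#'
#' Emits a McPAS-TCR-like table and a VDJdb-like table in which clones of
#' the public pool are annotated at `db_rate_public` and private-pool
#' clones at `db_rate_private`, plus decoy entries absent from the cohort.
#' Because downstream publicness is called empirically (two or more
#' patients, or the beta reference), the realised public-vs-private
#' annotation enrichment is attenuated relative to the configured rate
#' ratio.
#'
#' @param config A [synthetic_config()].
#' @param db_seed Seed for annotation draws (default `config$seed + 2`).
#' @param n_decoys Decoy database rows per database.
#' @return A list with tibbles `mcpas` (columns `CDR3.beta.aa`,
#'   `CDR3.alpha.aa`, `Pathology`, `Antigen.protein`) and `vdjdb` (columns
#'   `cdr3`, `gene`, `antigen.epitope`, `antigen.species`).
#' @export
generate_annotation_db <- function(config, db_seed = NULL, n_decoys = 200) {
  .validate_config(config)
  if (is.null(db_seed)) db_seed <- config$seed + 2L
  pools <- .make_pools(config)
  withr::with_seed(db_seed, {
    rate <- ifelse(pools$origin == "public", config$db_rate_public,
                   config$db_rate_private)
    hit <- stats::runif(nrow(pools)) < rate
    ann <- pools[hit, , drop = FALSE]
    n <- nrow(ann)
    mcpas_rows <- vdjdb_rows <- NULL
    if (n > 0) {
      ai <- sample(nrow(.ANTIGENS), n, replace = TRUE)
      dest <- sample(c("mcpas", "vdjdb", "both"), n, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
      in_mcpas <- dest %in% c("mcpas", "both")
      in_vdjdb <- dest %in% c("vdjdb", "both")
      mcpas_rows <- data.frame(
        CDR3.beta.aa = ifelse(ann$chain[in_mcpas] == "TRB",
                              ann$cdr3_aa[in_mcpas], ""),
        CDR3.alpha.aa = ifelse(ann$chain[in_mcpas] == "TRA",
                               ann$cdr3_aa[in_mcpas], ""),
        Pathology = .ANTIGENS$species[ai[in_mcpas]],
        Antigen.protein = .ANTIGENS$antigen[ai[in_mcpas]],
        stringsAsFactors = FALSE
      )
      mcpas_rows <- mcpas_rows[mcpas_rows$CDR3.beta.aa != "" |
                                 mcpas_rows$CDR3.alpha.aa != "", , drop = FALSE]
      vdjdb_rows <- data.frame(
        cdr3 = ann$cdr3_aa[in_vdjdb],
        gene = ann$chain[in_vdjdb],
        antigen.epitope = .ANTIGENS$antigen[ai[in_vdjdb]],
        antigen.species = .ANTIGENS$species[ai[in_vdjdb]],
        stringsAsFactors = FALSE
      )
    }
    ## decoys not present in any pool
    dec <- .random_cdr3(2 * n_decoys)
    dec <- setdiff(dec, pools$cdr3_aa)
    dec_m <- utils::head(dec, n_decoys)
    dec_v <- utils::tail(dec, n_decoys)
    am <- sample(nrow(.ANTIGENS), length(dec_m), replace = TRUE)
    av <- sample(nrow(.ANTIGENS), length(dec_v), replace = TRUE)
    mcpas <- rbind(mcpas_rows, data.frame(
      CDR3.beta.aa = dec_m, CDR3.alpha.aa = "",
      Pathology = .ANTIGENS$species[am],
      Antigen.protein = .ANTIGENS$antigen[am], stringsAsFactors = FALSE))
    vdjdb <- rbind(vdjdb_rows, data.frame(
      cdr3 = dec_v, gene = sample(c("TRA", "TRB"), length(dec_v),
                                  replace = TRUE),
      antigen.epitope = .ANTIGENS$antigen[av],
      antigen.species = .ANTIGENS$species[av], stringsAsFactors = FALSE))
    list(mcpas = tibble::as_tibble(mcpas), vdjdb = tibble::as_tibble(vdjdb))
  })
}
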