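# End-to-end orchestration: simulate (or ingest) repertoires, run every
# analysis stage, and write a structured report directory.
#
# Config schema (R list or YAML file):
#   seed: integer root seed
#   subjects: list of {id, species_preset, locus, n_clones,
#             n_reads_per_compartment} (simulated inputs), or
#   inputs: list of {id, species, lymph_node, spleen} AIRR TSV paths
#   analyses: named logicals: stats, model, diversity, sharing (default all)
#   figures: write PNG figures (default TRUE)
#   model_training_n: records per repertoire for model inference
#   rarefaction_fractions: numeric vector
# Outputs under output_dir: repertoires/*.tsv, truth/*.json, stats/*.tsv,
# models/*.json, diversity/*.tsv, sharing/*.tsv, figures/*.png, run_log.tsv
# and summary.json. Deterministic given the config.

#' Default synthetic pipeline configuration
#'
#' Three rat-like subjects and two human-like subjects, two tissue
#' compartments each, 20,000 reads per compartment.
#'
#' @param seed root seed.
#' @param n_reads_per_compartment reads per tissue compartment.
#' @param n_clones founder clones per subject.
#' @return config list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1, n_reads_per_compartment = 20000,
                                    n_clones = 10000) {
  list(
    seed = seed,
    subjects = c(
      lapply(1:3, function(i) list(id = paste0("OR", i),
                                   species_preset = "omnirat_like",
                                   locus = "IGH",
                                   n_clones = n_clones,
                                   n_reads_per_compartment = n_reads_per_compartment)),
      lapply(1:2, function(i) list(id = paste0("HU", i),
                                   species_preset = "human_like",
                                   locus = "IGH",
                                   n_clones = n_clones,
                                   n_reads_per_compartment = n_reads_per_compartment))
    ),
    analyses = list(stats = TRUE, model = TRUE, diversity = TRUE, sharing = TRUE),
    figures = TRUE,
    model_training_n = 10000,
    rarefaction_fractions = seq(0.1, 1, by = 0.1)
  )
}

validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  bad <- setdiff(names(config),
                 c("seed", "subjects", "inputs", "analyses", "figures",
                   "model_training_n", "rarefaction_fractions"))
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$subjects) && is.null(config$inputs)) {
    stop("config needs either 'subjects' (simulation) or 'inputs' (AIRR files)")
  }
  config$seed <- config$seed %||% 1
  defaults <- list(stats = TRUE, model = TRUE, diversity = TRUE, sharing = TRUE)
  config$analyses <- utils::modifyList(defaults, config$analyses %||% list())
  config$figures <- config$figures %||% TRUE
  config$model_training_n <- config$model_training_n %||% 10000
  config$rarefaction_fractions <- config$rarefaction_fractions %||% seq(0.1, 1, by = 0.1)
  config
}

#' Run the full comparative-repertoire pipeline
#'
#' Simulates (or ingests) per-subject two-compartment repertoires, then
#' runs the enabled analysis stages: gene-usage profiling with z-score
#' clustering, CDR3/insertion statistics, recombination-model inference
#' with pairwise complete KL divergences, clonotype diversity (incidence,
#' Chao2, rarefaction) and clonotype sharing. Record counts are conserved
#' and logged at every stage; the run is deterministic given the config.
#'
#' @param config config list or path to a YAML file (see
#'   [default_pipeline_config()] for the schema).
#' @param output_dir report directory (created).
#' @param seed optional override of the config seed.
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, output_dir, seed = NULL) {
  config <- validate_pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  root_seed <- config$seed
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("repertoires", "stats", "models", "diversity", "sharing", "figures")) {
    dir.create(file.path(output_dir, d), showWarnings = FALSE)
  }
  log_rows <- list()
  log_stage <- function(stage, detail, n_in, n_kept) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, detail = detail,
      n_input = n_in, n_kept = n_kept, n_rejected = n_in - n_kept)
  }
  summary <- list(seed = root_seed, subjects = list())

  # ---- inputs: simulate or ingest -------------------------------------
  subjects <- list()
  if (!is.null(config$subjects)) {
    for (i in seq_along(config$subjects)) {
      sc <- config$subjects[[i]]
      cfg <- simulator_config(
        species_preset = sc$species_preset,
        locus = sc$locus %||% "IGH",
        n_clones = sc$n_clones %||% 2000,
        n_reads_per_compartment = sc$n_reads_per_compartment %||% 20000,
        seed = sub_seed(root_seed, 100 + i),
        subject_id = sc$id
      )
      sim <- simulate_repertoire(cfg)
      for (tis in c("lymph_node", "spleen")) {
        write_airr(sim[[tis]], file.path(output_dir, "repertoires",
                                         paste0(sc$id, "_", tis, ".tsv")))
      }
      truth_path <- file.path(output_dir, "repertoires", paste0(sc$id, "_truth.tsv"))
      readr::write_tsv(sim$truth$clones, truth_path, progress = FALSE)
      write_model(sim$truth$model, file.path(output_dir, "models",
                                             paste0(sc$id, "_true_model.json")))
      subjects[[sc$id]] <- list(id = sc$id, species = sc$species_preset,
                                lymph_node = sim$lymph_node, spleen = sim$spleen)
      log_stage("simulate", sc$id, 2L * cfg$n_reads_per_compartment,
                n_records(sim$lymph_node) + n_records(sim$spleen))
    }
  } else {
    for (i in seq_along(config$inputs)) {
      sc <- config$inputs[[i]]
      ln <- read_airr(sc$lymph_node, locus = sc$locus %||% "IGH",
                      subject_id = sc$id, tissue = "lymph_node",
                      species = sc$species %||% "unknown")
      sp <- read_airr(sc$spleen, locus = sc$locus %||% "IGH",
                      subject_id = sc$id, tissue = "spleen",
                      species = sc$species %||% "unknown")
      subjects[[sc$id]] <- list(id = sc$id, species = sc$species %||% "unknown",
                                lymph_node = ln, spleen = sp)
      log_stage("ingest", sc$id,
                n_records(ln) + n_records(sp) + sum(ln$rejections$n) + sum(sp$rejections$n),
                n_records(ln) + n_records(sp))
    }
  }
  species_of <- vapply(subjects, function(s) s$species, character(1))
  all_reps <- list()
  for (s in subjects) {
    all_reps[[paste(s$id, "lymph_node", sep = ".")]] <- s$lymph_node
    all_reps[[paste(s$id, "spleen", sep = ".")]] <- s$spleen
  }

  # ---- stats ----------------------------------------------------------
  if (isTRUE(config$analyses$stats)) {
    usage_tabs <- list()
    for (seg in c("V", "D", "J")) {
      profs <- lapply(all_reps, gene_usage, segment = seg)
      mat <- usage_matrix(profs)
      clust <- zscore_and_cluster(mat)
      readr::write_tsv(tibble::as_tibble(clust$z, rownames = "gene"),
                       file.path(output_dir, "stats", paste0("usage_z_", seg, ".tsv")),
                       progress = FALSE)
      if (!is.null(clust$col_newick)) {
        writeLines(clust$col_newick,
                   file.path(output_dir, "stats", paste0("usage_dendrogram_", seg, ".nwk")))
      }
      usage_tabs[[seg]] <- clust
      if (isTRUE(config$figures) && requireNamespace("pheatmap", quietly = TRUE)) {
        grDevices::png(file.path(output_dir, "figures", paste0("usage_", seg, ".png")),
                       width = 900, height = 700)
        pheatmap::pheatmap(usage_tabs[[seg]]$z, clustering_method = "average",
                           main = paste(seg, "gene usage (z-score)"))
        grDevices::dev.off()
      }
    }
    per_rep <- dplyr::bind_rows(lapply(names(all_reps), function(lbl) {
      r <- all_reps[[lbl]]
      cd <- length_distribution(r, "cdr3_length")
      n1 <- length_distribution(r, "n1_length")
      n2 <- length_distribution(r, "n2_length")
      iso <- isotype_frequencies(r)
      tibble::tibble(
        repertoire = lbl,
        mean_cdrh3 = cd$mean, mean_n1 = n1$mean, mean_n2 = n2$mean,
        d3j6_frequency = family_pair_frequency(r),
        igg_frequency = iso$frequency[iso$isotype == "IgG"]
      )
    }))
    readr::write_tsv(per_rep, file.path(output_dir, "stats", "repertoire_stats.tsv"),
                     progress = FALSE)
    mut <- dplyr::bind_rows(lapply(names(all_reps), function(lbl) {
      dplyr::mutate(mutation_summary(all_reps[[lbl]]), repertoire = lbl)
    }))
    readr::write_tsv(mut, file.path(output_dir, "stats", "mutation_summary.tsv"),
                     progress = FALSE)
    summary$stats <- list(
      repertoire_stats = per_rep,
      top_level_split = top_level_split(usage_tabs$V$col_hclust)
    )
    log_stage("stats", "all repertoires",
              sum(vapply(all_reps, n_records, integer(1))),
              sum(vapply(all_reps, n_records, integer(1), productive_only = TRUE)))
  }

  # ---- recombination models -------------------------------------------
  if (isTRUE(config$analyses$model)) {
    models <- list()
    for (id in names(subjects)) {
      pooled <- repertoire(dplyr::bind_rows(subjects[[id]]$lymph_node$records,
                                            subjects[[id]]$spleen$records),
                           subject_id = id, tissue = "pooled",
                           locus = subjects[[id]]$lymph_node$locus,
                           species = subjects[[id]]$species,
                           germline = subjects[[id]]$lymph_node$germline)
      train <- select_unmutated(pooled, n = config$model_training_n,
                                seed = sub_seed(root_seed, 300))
      models[[id]] <- infer_model(train)
      write_model(models[[id]], file.path(output_dir, "models",
                                          paste0(id, "_inferred_model.json")))
      log_stage("model", id, n_records(pooled), attr(train, "n_selected"))
    }
    ids <- names(models)
    klmat <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (p in ids) for (q in ids) {
      if (p != q) klmat[p, q] <- kl_complete(models[[p]], models[[q]])
    }
    readr::write_tsv(tibble::as_tibble(klmat, rownames = "model_p"),
                     file.path(output_dir, "models", "kl_complete_pairwise.tsv"),
                     progress = FALSE)
    intra <- function(sp) {
      sel <- ids[species_of[ids] == sp]
      if (length(sel) < 2) return(NA_real_)
      vals <- klmat[sel, sel]
      mean(vals[row(vals) != col(vals)])
    }
    sp_names <- unique(species_of)
    inter <- NA_real_
    if (length(sp_names) == 2) {
      a <- ids[species_of[ids] == sp_names[1]]
      b <- ids[species_of[ids] == sp_names[2]]
      inter <- mean(c(klmat[a, b, drop = FALSE], klmat[b, a, drop = FALSE]))
    }
    summary$model <- list(
      kl_intra = stats::setNames(lapply(sp_names, intra), sp_names),
      kl_inter_species = inter
    )
  }

  # ---- diversity ------------------------------------------------------
  if (isTRUE(config$analyses$diversity)) {
    div_rows <- list()
    for (id in names(subjects)) {
      ct_ln <- assign_clonotypes(subjects[[id]]$lymph_node)
      ct_sp <- assign_clonotypes(subjects[[id]]$spleen)
      inc <- build_incidence(ct_ln, ct_sp)
      est <- chao2(inc)
      rar <- rarefaction(dplyr::bind_rows(ct_ln, ct_sp) |>
                           dplyr::group_by(.data$key) |>
                           dplyr::summarise(n_reads = sum(.data$n_reads),
                                            .groups = "drop"),
                         fractions = config$rarefaction_fractions,
                         seed = sub_seed(root_seed, 400))
      readr::write_tsv(rar, file.path(output_dir, "diversity",
                                      paste0(id, "_rarefaction.tsv")),
                       progress = FALSE)
      div_rows[[id]] <- tibble::tibble(
        subject = id, S_obs = inc$S_obs, Q1 = inc$Q1, Q2 = inc$Q2,
        chao2 = est$estimate)
    }
    div <- dplyr::bind_rows(div_rows)
    readr::write_tsv(div, file.path(output_dir, "diversity", "chao2.tsv"),
                     progress = FALSE)
    summary$diversity <- div
    log_stage("diversity", "chao2 per subject", nrow(div), nrow(div))
  }

  # ---- sharing --------------------------------------------------------
  if (isTRUE(config$analyses$sharing)) {
    clonos <- lapply(subjects, function(s) {
      dplyr::bind_rows(assign_clonotypes(s$lymph_node),
                       assign_clonotypes(s$spleen)) |>
        dplyr::distinct(.data$key, .keep_all = TRUE)
    })
    sp_names <- unique(species_of)
    focal <- names(clonos)[species_of == sp_names[1]]
    pair_rows <- list()
    if (length(focal) >= 2) {
      cmb <- utils::combn(focal, 2)
      for (k in seq_len(ncol(cmb))) {
        ps <- pairwise_sharing(clonos[[cmb[1, k]]], clonos[[cmb[2, k]]])
        pair_rows[[k]] <- tibble::tibble(
          a = cmb[1, k], b = cmb[2, k],
          intersection = ps$intersection,
          union_fraction = ps$fractions$union,
          mean_fraction = ps$fractions$mean)
      }
    }
    pair_tab <- dplyr::bind_rows(pair_rows)
    if (nrow(pair_tab) > 0) {
      readr::write_tsv(pair_tab, file.path(output_dir, "sharing", "pairwise.tsv"),
                       progress = FALSE)
    }
    mw <- if (length(focal) >= 2) multiway_sharing(clonos[focal]) else NULL
    if (!is.null(mw)) {
      readr::write_tsv(mw$regions, file.path(output_dir, "sharing", "venn_regions.tsv"),
                       progress = FALSE)
    }
    summary$sharing <- list(
      pairwise_union_fraction_mean = if (nrow(pair_tab) > 0) mean(pair_tab$union_fraction) else NA_real_,
      all_shared_fraction = if (!is.null(mw)) mw$all_shared_fraction else NA_real_
    )
    if (length(sp_names) == 2) {
      other <- names(clonos)[species_of == sp_names[2]]
      pool_keys <- unique(unlist(lapply(clonos[other], function(x) x$key)))
      po <- pool_overlap(clonos[focal], pool_keys)
      readr::write_tsv(po, file.path(output_dir, "sharing", "pool_overlap.tsv"),
                       progress = FALSE)
      animal_pool <- dplyr::bind_rows(clonos[focal]) |>
        dplyr::distinct(.data$key, .keep_all = TRUE)
      cmp <- suppressWarnings(compare_shared_unshared(animal_pool, pool_keys))
      summary$sharing$pool_overlap_combined <-
        po$fraction_in_pool[po$subject == "combined"]
      summary$sharing$shared_mean_cdrh3 <-
        if (!is.null(cmp$shared)) cmp$shared$mean_length else NA_real_
      summary$sharing$unshared_mean_cdrh3 <-
        if (!is.null(cmp$unshared)) cmp$unshared$mean_length else NA_real_
    }
    log_stage("sharing", "clonotype pools",
              sum(vapply(clonos, nrow, integer(1))),
              sum(vapply(clonos, nrow, integer(1))))
  }

  readr::write_tsv(dplyr::bind_rows(log_rows),
                   file.path(output_dir, "run_log.tsv"), progress = FALSE)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(summary)
}
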