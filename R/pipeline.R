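# End-to-end orchestration: load or simulate a study set, compute network /
# species / interaction metrics, run the group comparisons and fit the
# attachment contrast, writing plain-text reports with full seed provenance.

#' Per-species metric table for one network
#'
#' Raw and rank-normalized degree, nestedness-contribution z-score and (for
#' plants with a phylogeny) phylogenetic uniqueness, for both guilds. Ranks
#' are normalized within guild and network so 0 is the smallest value and 1
#' the largest.
#'
#' @param net a connected `bipartite_network`.
#' @param tree optional `phylo` object covering (some of) the plants.
#' @param n_contrib_reps focal-randomization ensemble size per species.
#' @param rng_seed integer seed.
#' @return `data.frame`: network_id, species, guild, exotic, degree,
#'   degree_rank, contribution_z, contribution_rank, uniqueness,
#'   uniqueness_rank.
#' @export
species_metric_table <- function(net, tree = NULL, n_contrib_reps = 100,
                                 rng_seed = 1L) {
  validate_network(net)
  b <- binary_structure(net)
  plants <- rownames(b); polls <- colnames(b)
  set.seed(rng_seed)
  z_all <- contribution_zscores(net, c(plants, polls), n_reps = n_contrib_reps)
  z_p <- z_all[seq_along(plants)]
  z_a <- z_all[length(plants) + seq_along(polls)]
  uniq <- if (!is.null(tree)) suppressWarnings(community_uniqueness(tree, net)) else
    setNames(rep(NA_real_, length(plants)), plants)
  plant_df <- data.frame(
    network_id = net$network_id, species = plants, guild = "plant",
    exotic = unname(net$exotic),
    degree = unname(rowSums(b)), degree_rank = rank_normalize(rowSums(b)),
    contribution_z = unname(z_p), contribution_rank = rank_normalize(z_p),
    uniqueness = unname(uniq), uniqueness_rank = rank_normalize(uniq),
    stringsAsFactors = FALSE)
  poll_df <- data.frame(
    network_id = net$network_id, species = polls, guild = "pollinator",
    exotic = NA,
    degree = unname(colSums(b)), degree_rank = rank_normalize(colSums(b)),
    contribution_z = unname(z_a), contribution_rank = rank_normalize(z_a),
    uniqueness = NA_real_, uniqueness_rank = NA_real_,
    stringsAsFactors = FALSE)
  out <- rbind(plant_df, poll_df)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' @param input_dir directory of `<name>.tsv` / `<name>.csv` interaction
#'   matrices with `<name>.meta` sidecars (see [read_network()]); `NULL` to
#'   simulate instead.
#' @param tree_path optional Newick plant phylogeny for the phylogenetic
#'   metrics.
#' @param synthetic named list of [generate_study_set()] arguments used when
#'   `input_dir` is `NULL`.
#' @param out_dir output directory for the report bundle.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param n_null_reps cell-model ensemble size behind relative nestedness.
#' @param n_contrib_reps focal ensemble size behind species contributions.
#' @param n_swap_reps swap replicates per network in the attachment contrast.
#' @param c_reps contribution ensemble size per swap replicate.
#' @param stages subset of `c("metrics", "interactions", "comparisons",
#'   "model")`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, tree_path = NULL,
                            synthetic = list(), out_dir = "exoticnets_out",
                            seed = 1L, n_null_reps = 1000,
                            n_contrib_reps = 100, n_swap_reps = 100,
                            c_reps = 25,
                            stages = c("metrics", "interactions",
                                       "comparisons", "model")) {
  stopifnot(all(stages %in% c("metrics", "interactions", "comparisons", "model")))
  structure(list(input_dir = input_dir, tree_path = tree_path,
                 synthetic = synthetic, out_dir = out_dir, seed = seed,
                 n_null_reps = n_null_reps, n_contrib_reps = n_contrib_reps,
                 n_swap_reps = n_swap_reps, c_reps = c_reps, stages = stages),
            class = "pipeline_config")
}

load_input_networks <- function(input_dir) {
  paths <- list.files(input_dir, pattern = "\\.(tsv|csv)$", full.names = TRUE)
  paths <- paths[!grepl("(^|/)(network_metrics|species_metrics|interactions|comparisons|prediction_grid)\\.tsv$", paths) &
                   !grepl("manifest", basename(paths))]
  if (length(paths) == 0) stop("no .tsv/.csv interaction matrices in ", input_dir)
  lapply(sort(paths), function(p) {
    meta <- sub("\\.(tsv|csv)$", ".meta", p)
    read_network(p, if (file.exists(meta)) meta else NULL)
  })
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: `metrics` (network-level and species-level TSVs), `interactions`
#' (interaction TSV plus dependence / preference regressions, quantitative
#' networks only), `comparisons` (Kruskal-Wallis invaded-vs-uninvaded tests
#' and prevalence trends), `model` (the empirical-vs-randomized attachment
#' contrast with a Table-2-style report and a prediction grid).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)

  set.seed(config$seed)
  stage_seeds <- setNames(as.list(sample.int(.Machine$integer.max, 5)),
                          c("simulate", "metrics", "species", "model", "grid"))

  nets <- withCallingHandlers({
    if (!is.null(config$input_dir)) {
      load_input_networks(config$input_dir)
    } else {
      args <- config$synthetic
      args$rng_seed <- stage_seeds$simulate
      do.call(generate_study_set, args)$networks
    }
  }, warning = function(w) {
    logf("[input] warning: %s", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  if (length(nets) == 0) stop("stage 'input' failed: no networks")
  tree <- if (!is.null(config$tree_path)) read_phylogeny(config$tree_path) else NULL
  logf("[input] %d networks loaded", length(nets))

  results <- list(networks = nets)
  paths <- character()
  catch_stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      logf("[%s] warning: %s", name, conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  invaded <- vapply(nets, function(n) any(n$exotic), TRUE)

  if ("metrics" %in% config$stages) {
    results$network_metrics <- catch_stage("metrics", {
      set.seed(stage_seeds$metrics)
      seeds <- sample.int(.Machine$integer.max, length(nets))
      nm <- do.call(rbind, lapply(seq_along(nets), function(i) {
        network_metrics(nets[[i]], n_null_reps = config$n_null_reps,
                        rng_seed = seeds[i])
      }))
      if (!is.null(tree)) {
        nm$phylo_diversity <- vapply(nets, function(n) {
          tryCatch(phylogenetic_diversity(tree, rownames(n$weights)),
                   error = function(e) NA_real_)
        }, 0)
      }
      nm$invaded <- invaded
      nm$n_exotic <- vapply(nets, function(n) sum(n$exotic), 0L)
      paths <<- c(paths, write_tsv(nm, file.path(config$out_dir, "network_metrics.tsv")))
      nm
    })
    results$species_metrics <- catch_stage("metrics", {
      set.seed(stage_seeds$species)
      seeds <- sample.int(.Machine$integer.max, length(nets))
      sm <- do.call(rbind, lapply(seq_along(nets), function(i) {
        species_metric_table(nets[[i]], tree = tree,
                             n_contrib_reps = config$n_contrib_reps,
                             rng_seed = seeds[i])
      }))
      paths <<- c(paths, write_tsv(sm, file.path(config$out_dir, "species_metrics.tsv")))
      sm
    })
  }

  if ("interactions" %in% config$stages) {
    quant <- nets[vapply(nets, function(n) n$quantitative, TRUE)]
    if (length(quant) > 0) {
      results$interactions <- catch_stage("interactions", {
        it <- do.call(rbind, lapply(quant, interaction_table))
        paths <<- c(paths, write_tsv(it, file.path(config$out_dir, "interactions.tsv")))
        it
      })
      it <- results$interactions
      if (length(unique(it$plant_exotic)) == 2) {
        results$dependence_plant <- catch_stage("interactions",
          dependence_regression(it, "plant"))
        results$dependence_pollinator <- catch_stage("interactions",
          dependence_regression(it, "pollinator"))
        results$preference_test <- catch_stage("interactions",
          preference_regression(it))
      } else {
        logf("[interactions] single exotic class; regressions skipped")
      }
    } else {
      logf("[interactions] no quantitative networks; stage skipped")
    }
  }

  if ("comparisons" %in% config$stages && "metrics" %in% config$stages) {
    results$comparisons <- catch_stage("comparisons", {
      nm <- results$network_metrics
      props <- c("S", "P", "A", "R", "C", "C_P", "C_A", "N", "N_star")
      if (!is.null(tree)) props <- c(props, "phylo_diversity")
      cmp <- do.call(rbind, lapply(props, function(pr) {
        kw <- kruskal_wallis(nm[[pr]], nm$invaded)
        data.frame(property = pr, chi_sq = kw$chi_sq, p_value = kw$p_value,
                   n_invaded = kw$group_sizes["invaded"],
                   n_uninvaded = kw$group_sizes["uninvaded"],
                   stringsAsFactors = FALSE)
      }))
      # species-level: exotic vs native plants on within-network ranks
      sm <- results$species_metrics
      pl <- sm[sm$guild == "plant", ]
      if (any(pl$exotic) && any(!pl$exotic)) {
        sp_props <- c(degree_rank = "degree_rank",
                      contribution_rank = "contribution_rank")
        if (!all(is.na(pl$uniqueness_rank))) {
          sp_props <- c(sp_props, uniqueness_rank = "uniqueness_rank")
        }
        cmp <- rbind(cmp, do.call(rbind, lapply(names(sp_props), function(pr) {
          kw <- kruskal_wallis(pl[[pr]], pl$exotic)
          data.frame(property = paste0("plant_", pr), chi_sq = kw$chi_sq,
                     p_value = kw$p_value,
                     n_invaded = kw$group_sizes["invaded"],
                     n_uninvaded = kw$group_sizes["uninvaded"],
                     stringsAsFactors = FALSE)
        })))
      }
      rownames(cmp) <- NULL
      paths <<- c(paths, write_tsv(cmp, file.path(config$out_dir, "comparisons.tsv")))
      cmp
    })
    if (sum(invaded) >= 3) {
      results$prevalence_trends <- catch_stage("comparisons", {
        nm <- results$network_metrics
        exotic_prevalence_trends(nm$S, nm$P, nm$A, nm$n_exotic)
      })
    }
  }

  if ("model" %in% config$stages) {
    if (sum(invaded) >= 2) {
      results$model <- catch_stage("model", {
        tab <- assemble_model_table(nets[invaded], n_reps = config$n_swap_reps,
                                    c_reps = config$c_reps,
                                    rng_seed = stage_seeds$model)
        fit <- fit_exotic_link_model(tab)
        report <- list(
          coefficients = fit$coefficients, random_rows = fit$random_table,
          ranef_variance = fit$ranef_var, n_obs = fit$n,
          converged = fit$converged, separation = fit$separation,
          n_swap_reps = config$n_swap_reps, c_reps = config$c_reps,
          seed = config$seed)
        jsonlite::write_json(report, file.path(config$out_dir, "attachment_model.json"),
                             auto_unbox = TRUE, digits = NA, dataframe = "rows")
        grid <- expand.grid(k = seq(0, 1, by = 0.1), c = seq(0, 1, by = 0.1))
        grid$p_empirical <- predict_attachment(fit, grid$k, grid$c, "empirical")
        grid$p_random <- predict_attachment(fit, grid$k, grid$c, "random")
        grid$relative_probability <- grid$p_empirical / grid$p_random
        paths <<- c(paths, write_tsv(grid, file.path(config$out_dir, "prediction_grid.tsv")))
        paths <<- c(paths, file.path(config$out_dir, "attachment_model.json"))
        fit
      })
    } else {
      logf("[model] fewer than 2 invaded networks; stage skipped")
    }
  }

  manifest <- list(seed = config$seed, n_null_reps = config$n_null_reps,
                   n_contrib_reps = config$n_contrib_reps,
                   n_swap_reps = config$n_swap_reps, c_reps = config$c_reps,
                   stages = config$stages, n_networks = length(nets),
                   stage_seeds = stage_seeds)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$paths <- c(paths, file.path(config$out_dir, "manifest.json"), log_path)
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic study set as matrix + sidecar
#' files), `metrics`, `analyze` (metrics + interactions + comparisons +
#' model) and `report` (metrics + comparisons only). Flags: `--in DIR`,
#' `--out DIR`, `--seed INT`, `--n-swap-reps INT` (default 100),
#' `--n-null-reps INT` (default 1000), `--n-contrib-reps INT`,
#' `--n-invaded INT`, `--n-uninvaded INT`, `--tree PATH`.
#'
#' @param args character vector (default: the actual command line).
#' @return exit status, invisibly (0 on success).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: exoticnets <simulate|metrics|analyze|report> [--flags]")
    return(invisible(1L))
  }
  cmd <- args[1]
  flags <- parse_flags(args[-1])
  getf <- function(name, default) {
    if (!is.null(flags[[name]])) flags[[name]] else default
  }
  seed <- as.integer(getf("seed", 1))
  out <- getf("out", "exoticnets_out")
  if (cmd == "simulate") {
    set.seed(seed)
    ss <- generate_study_set(n_invaded = as.integer(getf("n-invaded", 25)),
                             n_uninvaded = as.integer(getf("n-uninvaded", 34)),
                             rng_seed = seed)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    for (net in ss$networks) {
      write_network(net, file.path(out, paste0(net$network_id, ".tsv")),
                    file.path(out, paste0(net$network_id, ".meta")))
    }
    write_tsv(ss$manifest, file.path(out, "study_manifest.tsv"))
    message("wrote ", length(ss$networks), " networks to ", out)
    return(invisible(0L))
  }
  stages <- switch(cmd,
    metrics = "metrics",
    analyze = c("metrics", "interactions", "comparisons", "model"),
    report = c("metrics", "comparisons"),
    stop("unknown subcommand: ", cmd))
  config <- pipeline_config(
    input_dir = getf("in", NULL), tree_path = getf("tree", NULL),
    out_dir = out, seed = seed,
    n_null_reps = as.integer(getf("n-null-reps", 1000)),
    n_contrib_reps = as.integer(getf("n-contrib-reps", 100)),
    n_swap_reps = as.integer(getf("n-swap-reps", 100)),
    stages = stages)
  run_pipeline(config)
  message("pipeline complete; outputs in ", out)
  invisible(0L)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1
    } else {
      flags[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  flags
}
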