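# End-to-end orchestration: a configuration-driven run of the stages
# simulate / discretize / build-graph / solve / signatures / perturb /
# validate, writing deterministic TSV outputs stamped with the seed and a
# configuration fingerprint.

# Polynomial rolling hash over the deparsed configuration; a short stable
# fingerprint to stamp outputs with.
config_hash <- function(config) {
  # where output goes and how chatty the run is are not part of the
  # analysis identity
  config <- config[setdiff(names(config), c("out_dir", "quiet"))]
  txt <- paste(deparse(config), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(txt)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

stamp_file <- function(path, lines, hash, seed) {
  writeLines(c(sprintf("# config_hash=%s seed=%d", hash, seed), lines), path)
}

write_stamped_table <- function(df, path, hash, seed) {
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) apply(df, 1L, paste, collapse = "\t"))
  stamp_file(path, lines, hash, seed)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes, as configured: simulation of a synthetic study (graph,
#' observations, expression), discretization of an expression matrix,
#' subgraph extraction and compaction, per-profile consistency solving
#' with MCOS repairs, signature ranking, perturbation scoring and holdout
#' validation. Every stage is a pure function of the inputs, the
#' configuration and the seed; output files carry the seed and a
#' configuration fingerprint in a comment header.
#'
#' Configuration entries (a named list, or a path to a YAML file):
#' \describe{
#'   \item{seed}{integer, default 1.}
#'   \item{out_dir}{output directory (created), default `"signcon-out"`.}
#'   \item{simulate}{logical; generate graph/observations/expression from
#'     `spec` (arguments for [synthetic_spec()]).}
#'   \item{graph, roles, inputs}{paths to graph TSV files (when not
#'     simulating).}
#'   \item{observations}{directory of per-profile observation TSVs, or
#'     omitted when discretizing expression.}
#'   \item{expression, class_map}{expression TSV (genes x profiles) and a
#'     `profile  class` TSV; discretized with `k1`/`k2` (defaults 0.03 /
#'     0.2) against `ref_class` (default `"NPC"`).}
#'   \item{extract}{list with `sources` (and optional `targets`) enabling
#'     subgraph extraction; `compact: yes` enables compaction.}
#'   \item{stages}{character subset of `c("solve", "signatures",
#'     "perturb", "validate")`, default `"solve"`.}
#' }
#'
#' @param config Named list or path to a YAML configuration file.
#' @return Invisibly, a list with the graph, labelings, per-profile solve
#'   results and the stage outputs that were computed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "signcon-out"
  hash <- config_hash(config)
  stages <- config$stages %||% "solve"
  if ("signatures" %in% stages) stages <- union(stages, "solve")
  bound <- as.integer(config$bound %||% default_bound())
  log_msg <- function(...) {
    if (isTRUE(config$quiet)) return(invisible())
    message(sprintf("[signcon %s] ", hash), sprintf(...))
  }

  if (!isTRUE(config$simulate) && is.null(config$graph)) {
    stop("config must name a graph (or simulate: yes)")
  }
  if (!isTRUE(config$simulate) && is.null(config$expression) &&
      is.null(config$observations)) {
    stop("config must provide observations or an expression matrix")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  classes <- NULL
  truth <- NULL
  if (isTRUE(config$simulate)) {
    spec <- do.call(synthetic_spec,
                    c(config$spec %||% list(), list(seed = seed)))
    graph <- generate_graph(spec)
    sim <- generate_expression(graph, spec)
    expr <- sim$expr
    truth <- sim$truth
    classes <- expr$classes
    # observations: one planted-consistent labeling per profile
    labelings <- lapply(seq_along(classes), function(i) {
      plant_consistent_labeling(graph, seed = seed + i,
                                profile_id = names(classes)[i])$labeling
    })
    names(labelings) <- names(classes)
    write_signed_graph(graph, file.path(out_dir, "graph.tsv"),
                       file.path(out_dir, "roles.tsv"),
                       file.path(out_dir, "inputs.txt"))
    utils::write.table(data.frame(gene = rownames(expr$values),
                                  expr$values, check.names = FALSE),
                       file.path(out_dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    obs_dir <- file.path(out_dir, "observations")
    dir.create(obs_dir, showWarnings = FALSE)
    for (j in names(labelings)) {
      write_observations(labelings[[j]], file.path(obs_dir,
                                                   paste0(j, ".tsv")))
    }
  } else {
    if (is.null(config$graph)) stop("config must name a graph (or simulate: yes)")
    graph <- read_signed_graph(config$graph, config$roles, config$inputs)
    if (!is.null(config$expression)) {
      if (is.null(config$class_map)) {
        stop("class_map is required to discretize an expression matrix")
      }
      ed <- utils::read.delim(config$expression, check.names = FALSE)
      vals <- as.matrix(ed[, -1L, drop = FALSE])
      rownames(vals) <- as.character(ed[[1L]])
      cm <- utils::read.delim(config$class_map, colClasses = "character")
      classes <- stats::setNames(cm$class, cm$profile)
      expr <- expression_set(vals, classes)
      labelings <- lapply(discretize_profiles(
        differential_matrix(expr, ref_class = config$ref_class %||% "NPC"),
        k1 = config$k1 %||% 0.03, k2 = config$k2 %||% 0.2),
        restrict_labeling, nodes = graph$nodes)
    } else if (!is.null(config$observations)) {
      files <- list.files(config$observations, pattern = "\\.tsv$",
                          full.names = TRUE)
      if (length(files) == 0L) stop("no observation TSVs in ", config$observations)
      labelings <- lapply(files, read_observations)
      names(labelings) <- vapply(labelings, `[[`, character(1), "profile_id")
      if (!is.null(config$class_map)) {
        cm <- utils::read.delim(config$class_map, colClasses = "character")
        classes <- stats::setNames(cm$class, cm$profile)
      }
    } else {
      stop("config must provide observations or an expression matrix")
    }
  }
  if (any(c("signatures", "perturb") %in% stages) && is.null(classes)) {
    stop("stages 'signatures'/'perturb' require a class map")
  }
  log_msg("graph: %d nodes, %d edges; %d profile(s)",
          length(graph$nodes), nrow(graph$edges), length(labelings))

  if (!is.null(config$extract)) {
    graph <- extract_subgraph(graph, config$extract$sources,
                              config$extract$targets %||%
                                observable_genes(graph))
    log_msg("extracted subgraph: %d nodes, %d edges (%d target(s) dropped)",
            length(graph$nodes), nrow(graph$edges),
            length(attr(graph, "dropped_targets")))
  }
  if (isTRUE(config$compact)) {
    graph <- compact_graph(graph)
    log_msg("compacted graph: %d nodes, %d edges",
            length(graph$nodes), nrow(graph$edges))
  }
  labelings <- lapply(labelings, restrict_labeling, nodes = graph$nodes)

  out <- list(graph = graph, labelings = labelings, config_hash = hash)
  if ("solve" %in% stages) {
    solves <- lapply(labelings, function(b) {
      solve_consistency(graph, b, mode = "mcos", bound = bound)
    })
    out$solves <- solves
    df <- do.call(rbind, lapply(names(solves), function(j) {
      data.frame(profile = j, score = solves[[j]]$score,
                 node = names(solves[[j]]$projections),
                 class = unname(solves[[j]]$projections))
    }))
    write_stamped_table(df, file.path(out_dir, "projections.tsv"), hash, seed)
    log_msg("solved %d profile(s); MCOS scores: %s", length(solves),
            paste(vapply(solves, `[[`, integer(1), "score"), collapse = " "))
  }
  if ("signatures" %in% stages) {
    proj <- lapply(out$solves, `[[`, "projections")
    M <- build_prediction_matrix(proj, labelings, classes)
    cls_levels <- unique(classes[names(labelings)])
    ranked <- rank_assignments(M, class_a = cls_levels[1L],
                               class_b = cls_levels[2L], graph = graph)
    out$signatures <- list(M = M, ranked = ranked)
    write_prediction_matrix(M, file.path(out_dir, "prediction_matrix.tsv"))
    write_stamped_table(ranked, file.path(out_dir, "signatures.tsv"),
                        hash, seed)
  }
  if ("perturb" %in% stages) {
    cls_levels <- unique(classes[names(labelings)])
    pert <- top_perturbation_scores(graph, labelings, classes,
                                    q = config$q %||% 0.10,
                                    class_a = cls_levels[1L],
                                    class_b = cls_levels[2L], bound = bound)
    out$perturbation <- pert
    write_stamped_table(pert$scores, file.path(out_dir, "perturbation_sf.tsv"),
                        hash, seed)
    write_stamped_table(pert$table, file.path(out_dir, "perturbation_tps.tsv"),
                        hash, seed)
  }
  if ("validate" %in% stages) {
    set.seed(seed)
    reps <- as.integer(config$validate_reps %||% 20L)
    prec <- vapply(seq_len(reps), function(r) {
      b <- labelings[[sample.int(length(labelings), 1L)]]
      holdout_precision(graph, b, frac = config$frac %||% 0.5,
                        bound = bound)$precision
    }, numeric(1))
    base <- randomized_baseline(graph, labelings[[1L]],
                                frac = config$frac %||% 0.5,
                                reps = reps, seed = seed + 1L, bound = bound)
    out$validation <- list(precision = prec, baseline = base)
    write_stamped_table(data.frame(rep = seq_len(reps), precision = prec,
                                   baseline = base),
                        file.path(out_dir, "validation.tsv"), hash, seed)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
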