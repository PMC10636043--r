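# End-to-end orchestration: configuration, the in-memory pipeline, the
# disk-artifact runner used by the CLI, and the benchmark protocols.

#' Pipeline configuration
#'
#' Validates and assembles all module settings. Unknown keys are rejected.
#' Defaults follow the method's published hyperparameters: SVD dimensionality
#' 30, graph neighbors 50, propagation depth 3, critic/reconstructor hidden
#' width 256, projector hidden width 2048, learning rate 1e-4, clipping
#' ratio 0.6, match threshold 0.05 with a 1000-pair null.
#'
#' @param ... key = value overrides of the defaults listed below.
#' @return validated named list of class `align_config`.
#' @export
align_config <- function(...) {
  defaults <- list(
    svd_dim = 30, target_sum = 1e4, scale_clip = 10, min_counts = 1, hvg = 0,
    graph_mode = "knn", graph_K = 50, graph_K1 = NULL, graph_K2 = NULL,
    graph_radius = NULL, graph_mutual = FALSE,
    lgcn_L = 3,
    embed_dim = 50, hidden = 256, embed_hidden = 2048, lr = 1e-4,
    alpha = 0.5, clip_ratio = 0.6, steps = 250, weight_clip = 0.1,
    plateau_tol = 1e-4,
    coords_method = "icp", coords_rotate = 0, coords_scale = 1,
    coords_translate = c(0, 0), coords_max_iter = 50, coords_tol = 1e-6,
    match_K = NULL, match_threshold = 0.05, match_n_null = 1000,
    ablate = "none", seed = 0
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  stopifnot(cfg$svd_dim >= 1, cfg$lgcn_L >= 0,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$clip_ratio > 0, cfg$clip_ratio <= 1,
            cfg$graph_mode %in% c("knn", "radius"),
            cfg$coords_method %in% c("icp", "manual", "none", "external"))
  cfg$ablate <- match.arg(cfg$ablate, c("none", "no_lgcn", "no_discriminator"))
  class(cfg) <- "align_config"
  cfg
}

build_graph_for <- function(coords, cfg, which) {
  if (cfg$graph_mode == "radius") {
    return(build_radius_graph(coords, cfg$graph_radius))
  }
  K <- if (which == 1 && !is.null(cfg$graph_K1)) cfg$graph_K1
       else if (which == 2 && !is.null(cfg$graph_K2)) cfg$graph_K2
       else cfg$graph_K
  build_knn_graph(coords, K = min(K, nrow(coords) - 1L), mutual = cfg$graph_mutual)
}

#' Align two spatial slices
#'
#' Full pipeline: shared-feature SVD embedding (or external-embedding
#' pass-through), per-slice spatial graphs, lightweight graph convolution,
#' adversarial training of the shared projector, coordinate registration,
#' and probabilistic match calling. Deterministic for a fixed `cfg$seed`
#' (module seeds are fanned out with [derive_seed()]).
#'
#' @param s1,s2 `spatial_slice` objects (slice 2 is matched onto slice 1).
#' @param cfg an [align_config()].
#' @param transform optional precomputed `affine_transform` mapping slice-2
#'   coordinates into slice-1's frame (used when
#'   `cfg$coords_method = "external"`).
#' @return list of class `alignment_result`: `matches` (full match table),
#'   `best` (best match per cell), `model`, `transform`, `Z1`, `Z2`,
#'   `metrics` (when labels are present), `similarity` (per-cell score),
#'   and the `config`.
#' @export
align_slices <- function(s1, s2, cfg = align_config(), transform = NULL) {
  s1 <- filter_min_counts(s1, cfg$min_counts)
  s2 <- filter_min_counts(s2, cfg$min_counts)
  ep <- embed_pair(s1, s2, M = cfg$svd_dim, target_sum = cfg$target_sum,
                   scale_clip = cfg$scale_clip, hvg = cfg$hvg)
  g1 <- build_graph_for(s1$coords, cfg, 1)
  g2 <- build_graph_for(s2$coords, cfg, 2)
  L <- if (cfg$ablate == "no_lgcn") 0 else cfg$lgcn_L
  h <- holistic_pair(ep, g1, g2, L = L)
  tcfg <- train_config(embed_dim = cfg$embed_dim, hidden = cfg$hidden,
                       embed_hidden = cfg$embed_hidden, lr = cfg$lr,
                       alpha = cfg$alpha, clip_ratio = cfg$clip_ratio,
                       steps = cfg$steps, weight_clip = cfg$weight_clip,
                       plateau_tol = cfg$plateau_tol,
                       seed = derive_seed(cfg$seed, "model"),
                       ablate = cfg$ablate)
  model <- align_train(h$Xt1, h$Xt2, ep$X1, ep$X2, tcfg)

  t2 <- switch(cfg$coords_method,
    icp = icp_register(s1$coords, s2$coords,
                       max_iter = cfg$coords_max_iter, tol = cfg$coords_tol),
    manual = manual_transform(cfg$coords_rotate, cfg$coords_scale,
                              cfg$coords_translate,
                              center = colMeans(s2$coords)),
    none = identity_transform(),
    external = {
      if (is.null(transform)) stop("coords_method = 'external' needs a transform")
      transform
    })
  S2p <- apply_transform(s2$coords, t2)

  K <- if (is.null(cfg$match_K)) cfg$graph_K else cfg$match_K
  matches <- call_matches(model$Z1, model$Z2, s1$coords, S2p,
                          K = min(K, n_cells(s2)),
                          threshold = cfg$match_threshold,
                          n_null = cfg$match_n_null,
                          seed = derive_seed(cfg$seed, "null"))
  best <- best_matches(matches)
  metrics <- if (!is.null(s1$cell_type) || !is.null(s1$region))
    alignment_metrics(best, s1, s2) else NULL
  structure(
    list(matches = matches, best = best, model = model, transform = t2,
         Z1 = model$Z1, Z2 = model$Z2, graphs = list(g1 = g1, g2 = g2),
         metrics = metrics, similarity = similarity_score(best, n_cells(s1)),
         config = cfg),
    class = "alignment_result"
  )
}

#' @exportS3Method base::print
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result: %d -> %d cells, %d accepted matches (%.1f%% of candidates)\n",
              length(x$similarity), nrow(x$Z2), sum(x$matches$accepted),
              100 * mean(x$matches$accepted)))
  if (!is.null(x$metrics$joint_accuracy) && !is.na(x$metrics$joint_accuracy))
    cat(sprintf("  joint accuracy: %.3f\n", x$metrics$joint_accuracy))
  invisible(x)
}

#' Run an alignment and write its artifacts
#'
#' Reads two slice directories, runs [align_slices()], and writes to `out`:
#' `Z1.csv`, `Z2.csv`, `transform.txt`, `matches.tsv`, `best_matches.tsv`,
#' `metrics.json` (when labels are present) and `provenance.json` (config,
#' seed, package version).
#'
#' @param slice1,slice2 slice directory paths (see [read_slice()]).
#' @param out output directory.
#' @param cfg an [align_config()].
#' @return the `alignment_result`, invisibly.
#' @export
run_align <- function(slice1, slice2, out, cfg = align_config()) {
  s1 <- read_slice(slice1)
  s2 <- read_slice(slice2)
  res <- align_slices(s1, s2, cfg)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$Z1, file.path(out, "Z1.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(res$Z2, file.path(out, "Z2.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  write_transform(res$transform, file.path(out, "transform.txt"))
  write_matches(res$matches, file.path(out, "matches.tsv"))
  write_matches(res$best, file.path(out, "best_matches.tsv"))
  if (!is.null(res$metrics)) {
    m <- res$metrics
    for (key in c("type_confusion", "region_confusion")) {
      cm <- m$contingency[[key]]
      if (!is.null(cm))
        utils::write.table(as.data.frame.matrix(cm),
                           file.path(out, paste0(key, ".tsv")),
                           sep = "\t", quote = FALSE, col.names = NA)
    }
    m$contingency <- list(proportions = as.vector(m$contingency$proportions),
                          n_evaluated = m$contingency$n_evaluated)
    jsonlite::write_json(m, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  prov <- list(config = unclass(cfg), seed = cfg$seed,
               package_version = as.character(utils::packageVersion("slicealign")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(res)
}

#' Run a benchmark protocol on synthetic data
#'
#' Protocols mirror the published benchmark design:
#' \describe{
#'   \item{duplicate}{align a structured slice against its NB-noised,
#'     rotated duplicate across a theta grid; reports ground-truth accuracy
#'     and rotation recovery.}
#'   \item{split}{random disjoint halves of one slice; reports label
#'     accuracies (no per-cell truth exists).}
#'   \item{corruption}{duplicate task with graph edges randomly masked at
#'     increasing ratios.}
#'   \item{scaling}{duplicate task at increasing cell counts; reports
#'     wall-clock seconds.}
#' }
#'
#' @param task one of `"duplicate"`, `"split"`, `"corruption"`, `"scaling"`.
#' @param cfg an [align_config()] (per-repeat seeds are derived from
#'   `cfg$seed`).
#' @param synth a [synth_config()] for the generator.
#' @param theta_grid NB inverse-dispersion grid for the duplicate task.
#' @param mask_grid masking ratios for the corruption task.
#' @param size_grid cell counts for the scaling task.
#' @param repeats stochastic repeats per condition (default 8, as in the
#'   published protocol; lower for quick runs).
#' @return a tidy `data.frame`, one row per condition x repeat.
#' @export
run_benchmark <- function(task = c("duplicate", "split", "corruption", "scaling"),
                          cfg = align_config(), synth = synth_config(),
                          theta_grid = c(1e6, 10, 1),
                          mask_grid = seq(0.1, 0.9, by = 0.2),
                          size_grid = c(200, 400, 800),
                          repeats = 8) {
  task <- match.arg(task)
  rows <- list()
  base <- make_structured_slice(synth)
  add_row <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)

  dup_once <- function(theta, rep_i, slice = base, corruption = NULL) {
    seed_r <- derive_seed(cfg$seed, paste0(task, theta, "r", rep_i))
    s2 <- duplicate_with_noise(slice, theta, rotate_deg = synth$rotate_deg,
                               seed = seed_r)
    cfg_r <- cfg; cfg_r$seed <- seed_r
    res <- align_slices_maybe_corrupt(slice, s2, cfg_r, corruption, seed_r)
    acc <- ground_truth_accuracy(res$best$target)
    rot <- res$metrics$rotation_deg
    data.frame(theta = theta, repeat_i = rep_i,
               ground_truth_accuracy = acc,
               rotation_error_deg = abs(angle_diff(rot, synth$rotate_deg)),
               joint_accuracy = res$metrics$joint_accuracy)
  }

  if (task == "duplicate") {
    for (theta in theta_grid) for (r in seq_len(repeats))
      add_row(dup_once(theta, r))
  } else if (task == "split") {
    for (r in seq_len(repeats)) {
      seed_r <- derive_seed(cfg$seed, paste0("split", r))
      sp <- split_slice(base, seed = seed_r)
      cfg_r <- cfg; cfg_r$seed <- seed_r
      res <- align_slices(sp$s1, sp$s2, cfg_r)
      add_row(repeat_i = r,
              type_accuracy = res$metrics$type_accuracy,
              region_accuracy = res$metrics$region_accuracy,
              joint_accuracy = res$metrics$joint_accuracy)
    }
  } else if (task == "corruption") {
    for (mr in mask_grid) for (r in seq_len(repeats))
      add_row(cbind(mask_ratio = mr, dup_once(synth$nb_theta, r, corruption = mr)))
  } else if (task == "scaling") {
    for (n in size_grid) for (r in seq_len(repeats)) {
      t0 <- proc.time()[["elapsed"]]
      sub <- subsample_slice(base, min(n, n_cells(base)),
                             seed = derive_seed(cfg$seed, paste0("sub", n, r)))
      row <- dup_once(synth$nb_theta, r, slice = sub)
      add_row(cbind(n_cells = n_cells(sub), row,
                    seconds = proc.time()[["elapsed"]] - t0))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Duplicate-task runner with optional graph corruption: graphs are built as
# usual, then masked before propagation/training.
align_slices_maybe_corrupt <- function(s1, s2, cfg, mask_ratio, seed) {
  if (is.null(mask_ratio)) return(align_slices(s1, s2, cfg))
  ep <- embed_pair(s1, s2, M = cfg$svd_dim, target_sum = cfg$target_sum,
                   scale_clip = cfg$scale_clip, hvg = cfg$hvg)
  g1 <- corrupt_graph(build_graph_for(s1$coords, cfg, 1), mask_ratio,
                      seed = derive_seed(seed, "mask1"))
  g2 <- corrupt_graph(build_graph_for(s2$coords, cfg, 2), mask_ratio,
                      seed = derive_seed(seed, "mask2"))
  L <- if (cfg$ablate == "no_lgcn") 0 else cfg$lgcn_L
  h <- holistic_pair(ep, g1, g2, L = L)
  tcfg <- train_config(embed_dim = cfg$embed_dim, hidden = cfg$hidden,
                       embed_hidden = cfg$embed_hidden, lr = cfg$lr,
                       alpha = cfg$alpha, clip_ratio = cfg$clip_ratio,
                       steps = cfg$steps, weight_clip = cfg$weight_clip,
                       plateau_tol = cfg$plateau_tol,
                       seed = derive_seed(cfg$seed, "model"), ablate = cfg$ablate)
  model <- align_train(h$Xt1, h$Xt2, ep$X1, ep$X2, tcfg)
  t2 <- icp_register(s1$coords, s2$coords, max_iter = cfg$coords_max_iter,
                     tol = cfg$coords_tol)
  S2p <- apply_transform(s2$coords, t2)
  K <- if (is.null(cfg$match_K)) cfg$graph_K else cfg$match_K
  matches <- call_matches(model$Z1, model$Z2, s1$coords, S2p,
                          K = min(K, n_cells(s2)),
                          threshold = cfg$match_threshold,
                          n_null = cfg$match_n_null,
                          seed = derive_seed(cfg$seed, "null"))
  best <- best_matches(matches)
  structure(list(matches = matches, best = best, model = model,
                 transform = t2, Z1 = model$Z1, Z2 = model$Z2,
                 graphs = list(g1 = g1, g2 = g2),
                 metrics = alignment_metrics(best, s1, s2),
                 similarity = similarity_score(best, n_cells(s1)),
                 config = cfg),
            class = "alignment_result")
}
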