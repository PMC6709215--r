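#' Build and validate a pipeline configuration
#'
#' One configuration drives a full experiment: synthetic cohort generation,
#' preprocessing, connectivity inference, network metrics, optional
#' theta-model ictogenicity, and group statistics. Every stochastic stage
#' must carry an explicit seed. Configurations round-trip losslessly
#' through YAML ([write_config()] / [read_config()]).
#'
#' @param cohort List: `stages` (subset of day0/day7/day28/sham),
#'   `n_subjects` (NULL for stage defaults), `seed`, `layout_rows`,
#'   `layout_cols`, `fs`, `duration_s`.
#' @param preprocess List: `band`, `notch`, `order`, `seg_len_s`,
#'   `min_gap_s`, `max_segments`.
#' @param connectivity List: `methods`, `n_windows`, `win_len_s`,
#'   `n_surrogate_sets`, `alpha`, `seed`.
#' @param metrics List: `pct` (top-edge percentage), `mds_k`.
#' @param thetasim List: `enabled`, `n_steps`, `n_runs`, `dt`,
#'   `active_window`, `seed`.
#' @param stats List: `q`, `alternative`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(
    cohort = list(stages = c("day0", "day28"), n_subjects = NULL,
                  seed = NULL, layout_rows = 5, layout_cols = 6,
                  fs = 4000, duration_s = 60),
    preprocess = list(band = c(1, 150), notch = c(50, 100, 150), order = 2,
                      seg_len_s = 1, min_gap_s = 1, max_segments = 83),
    connectivity = list(methods = c("abs", "max", "min"), n_windows = 21,
                        win_len_s = 0.5, n_surrogate_sets = 100,
                        alpha = 0.05, seed = NULL),
    metrics = list(pct = 5, mds_k = 3),
    thetasim = list(enabled = FALSE, n_steps = 4e5, n_runs = 10, dt = 0.01,
                    active_window = 0.5, seed = NULL),
    stats = list(q = 0.1, alternative = "two.sided")) {
  cfg <- structure(list(cohort = cohort, preprocess = preprocess,
                        connectivity = connectivity, metrics = metrics,
                        thetasim = thetasim, stats = stats),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  need_seed <- c("cohort", "connectivity")
  if (isTRUE(cfg$thetasim$enabled)) need_seed <- c(need_seed, "thetasim")
  for (st in need_seed)
    if (is.null(cfg[[st]]$seed))
      stop("config stage '", st, "' is stochastic but has no seed")
  stopifnot(all(cfg$cohort$stages %in% c("day0", "day7", "day28", "sham")),
            all(cfg$connectivity$methods %in% c("abs", "max", "min")))
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline from a configuration
#'
#' Generates synthetic cohorts for the configured stages, preprocesses each
#' recording (average re-reference, notch + band-pass, background segment
#' selection), infers the configured connectivity variants per recording,
#' computes node-level and global network metrics, median matrices, top
#' edges and contralateral fractions, a Frobenius-distance MDS embedding
#' across recordings, optionally the theta-model omega_50 calibration and
#' node ictogenicity per recording, and group statistics against the day0
#' cohort. All tabular outputs are written as CSV under `out_dir`, and a
#' JSON manifest records the configuration, seeds, and an MD5 checksum per
#' output file; re-running the same configuration reproduces identical
#' checksums.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  layout <- make_layout(cfg$cohort$layout_rows, cfg$cohort$layout_cols)
  cohorts <- run_stage("cohort", {
    lapply(stats::setNames(nm = cfg$cohort$stages), function(st)
      generate_cohort(st, cfg$cohort$n_subjects, seed = cfg$cohort$seed,
                      layout = layout, fs = cfg$cohort$fs,
                      duration_s = cfg$cohort$duration_s))
  })

  seg_sets <- run_stage("preprocess", {
    lapply(cohorts, function(recs) lapply(recs, function(r) {
      r <- rereference_average(r)
      r <- filter_recording(r, cfg$preprocess$notch, cfg$preprocess$band,
                            cfg$preprocess$order)
      select_segments(r, cfg$preprocess$seg_len_s, cfg$preprocess$min_gap_s,
                      cfg$preprocess$max_segments)
    }))
  })

  conn <- run_stage("connectivity", {
    res <- list()
    for (st in names(seg_sets)) {
      res[[st]] <- lapply(seq_along(seg_sets[[st]]), function(k)
        recording_connectivity_all(
          seg_sets[[st]][[k]],
          n_windows = cfg$connectivity$n_windows,
          win_len_s = cfg$connectivity$win_len_s,
          n_surrogate_sets = cfg$connectivity$n_surrogate_sets,
          alpha = cfg$connectivity$alpha,
          seed = derive_seeds(cfg$connectivity$seed, 1,
                              salt = match(st, names(seg_sets)) * 100 + k)))
    }
    res
  })
  methods <- cfg$connectivity$methods

  run_stage("metrics", {
    rows <- list(); qc <- list(); ctf <- list()
    for (st in names(conn)) for (k in seq_along(conn[[st]])) {
      for (m in methods) {
        C <- conn[[st]][[k]][[m]]
        gm <- global_measures(C)
        rows[[length(rows) + 1L]] <- data.frame(
          stage = st, subject = k, method = toupper(m),
          measure = names(gm), value = unname(gm))
        qc[[length(qc) + 1L]] <- data.frame(
          stage = st, subject = k, method = toupper(m),
          n_segments = C$n_segments_used,
          n_nonzero = sum(C$weights != 0))
        ctf[[length(ctf) + 1L]] <- data.frame(
          stage = st, subject = k, method = toupper(m),
          contralateral_top_fraction =
            contralateral_top_fraction(C, layout, cfg$metrics$pct))
      }
    }
    emit(do.call(rbind, rows), "global_measures.csv")
    emit(do.call(rbind, qc), "qc.csv")
    emit(do.call(rbind, ctf), "contralateral_fraction.csv")

    imb <- list()
    for (st in names(conn)) for (k in seq_along(conn[[st]]))
      for (m in methods) {
        di <- degree_imbalance(conn[[st]][[k]][[m]])
        di$stage <- st; di$subject <- k; di$method <- toupper(m)
        imb[[length(imb) + 1L]] <- di
      }
    emit(do.call(rbind, imb), "degree_imbalance.csv")

    for (m in methods) {
      med <- lapply(conn, function(x)
        median_matrix(lapply(x, `[[`, m)))
      te <- do.call(rbind, lapply(names(med), function(st) {
        e <- top_edges(med[[st]], cfg$metrics$pct)
        if (nrow(e)) cbind(stage = st, e) else NULL
      }))
      if (!is.null(te)) emit(te, paste0("top_edges_", m, ".csv"))
      # Frobenius distances + MDS over all recordings of this method
      mats <- unlist(lapply(conn, function(x) lapply(x, `[[`, m)),
                     recursive = FALSE)
      if (length(mats) >= 4) {
        n <- length(mats)
        D <- matrix(0, n, n)
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
          D[i, j] <- D[j, i] <- frobenius_distance(mats[[i]], mats[[j]])
        emb <- mds_embed(D, k = min(cfg$metrics$mds_k, n - 1))
        co <- as.data.frame(emb$coordinates)
        names(co) <- paste0("dim", seq_len(ncol(co)))
        co$recording <- names(mats)
        co$R <- emb$R
        emit(co, paste0("mds_", m, ".csv"))
      }
    }
  })

  ni_tabs <- NULL
  if (isTRUE(cfg$thetasim$enabled)) ni_tabs <- run_stage("thetasim", {
    pars <- theta_params(n_steps = cfg$thetasim$n_steps,
                         n_runs = cfg$thetasim$n_runs,
                         dt = cfg$thetasim$dt,
                         active_window = cfg$thetasim$active_window)
    out <- list()
    for (st in names(conn)) for (k in seq_along(conn[[st]]))
      for (m in methods) {
        C <- conn[[st]][[k]][[m]]
        if (all(C$weights == 0)) next
        sd_seed <- derive_seeds(cfg$thetasim$seed, 1,
                                salt = match(st, names(conn)) * 100 + k)
        cal <- calibrate_omega(C, pars, seed = sd_seed)
        nip <- node_ictogenicity(C, cal$omega_50, pars, seed = sd_seed + 1)
        df <- nip$ni
        df$stage <- st; df$subject <- k; df$method <- toupper(m)
        df$omega_50 <- cal$omega_50; df$bni_achieved <- cal$bni_achieved
        out[[length(out) + 1L]] <- df
      }
    tab <- do.call(rbind, out)
    emit(tab, "node_ictogenicity.csv")
    tab
  })

  run_stage("stats", {
    if ("day0" %in% names(conn)) {
      others <- setdiff(names(conn), "day0")
      node_mat <- function(st, m) t(vapply(conn[[st]], function(x)
        degree_imbalance(x[[m]])$degree_imbalance,
        numeric(layout$n_channels)))
      cmp <- list()
      for (st in others) for (m in methods) {
        res <- compare_nodes(node_mat("day0", m), node_mat(st, m),
                             alternative = cfg$stats$alternative,
                             q = cfg$stats$q)
        res$comparison <- paste0("day0_vs_", st)
        res$method <- toupper(m); res$quantity <- "degree_imbalance"
        cmp[[length(cmp) + 1L]] <- res
      }
      if (!is.null(ni_tabs)) {
        for (st in others) for (m in methods) {
          pick <- function(s) {
            sub <- ni_tabs[ni_tabs$stage == s & ni_tabs$method == toupper(m), ]
            if (!nrow(sub)) return(NULL)
            do.call(rbind, lapply(split(sub$ni, sub$subject), rbind))
          }
          a <- pick("day0"); b <- pick(st)
          if (is.null(a) || is.null(b)) next
          res <- compare_nodes(a, b, alternative = "greater",
                               q = cfg$stats$q)
          res$comparison <- paste0("day0_vs_", st)
          res$method <- toupper(m); res$quantity <- "ni"
          cmp[[length(cmp) + 1L]] <- res
        }
      }
      if (length(cmp)) emit(do.call(rbind, cmp), "node_comparisons.csv")
    }
  })

  manifest <- list(
    package = "ictonet",
    version = as.character(utils::packageVersion("ictonet")),
    config = unclass(cfg),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
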