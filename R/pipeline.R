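#' Pipeline orchestration: simulate -> (render/detect) -> track -> dynamics -> stats
#'
#' Stable CSV schemas between stages, a reproducible end-to-end driver and
#' the group-inference battery over the resulting dynamics tables.
#'
#' @name pipeline
NULL

# canonical inter-stage schemas (column name -> required)
.schemas <- list(
  observations = c("axon_id", "session", "type", "arc_pos_um",
                   "intensity_ratio", "protrusion_len_um", "z_extent_planes"),
  tracks = c("track_id", "axon_id", "type", "session", "observed", "size",
             "z_extent_planes", "arc_pos_um", "present", "event"),
  axons = c("axon_id", "group", "type", "length_um"),
  density = c("axon_id", "session", "n_total", "length_um", "density_per_um",
              "day", "group", "type"),
  intervals = c("axon_id", "day", "session_a", "session_b", "n_a", "n_b",
                "gains", "losses", "turnover", "gain_frac", "loss_frac",
                "group", "type"),
  results = c("family", "measure", "comparison", "test", "statistic", "value",
              "df", "p", "effect_size", "adjusted_alpha", "significant")
)

#' Write a pipeline table with schema validation
#'
#' Tables are comma-separated UTF-8 with "." decimals; columns are written in
#' canonical schema order.
#'
#' @param df Data frame.
#' @param path Output CSV path.
#' @param schema One of `"observations"`, `"tracks"`, `"axons"`, `"density"`,
#'   `"intervals"`, `"results"`.
#' @export
write_table <- function(df, path, schema) {
  cols <- .schemas[[match.arg(schema, names(.schemas))]]
  missing <- setdiff(cols, names(df))
  if (length(missing)) stop("missing required columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), cols)
  if (length(extra)) stop("unknown columns: ", paste(extra, collapse = ", "))
  utils::write.csv(df[, cols, drop = FALSE], path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Read a pipeline table, validating its header against the schema
#'
#' Reordered columns are accepted (and restored to canonical order); unknown
#' or missing columns are an error.
#'
#' @param path CSV path.
#' @param schema Schema name (see [write_table()]).
#' @return Data frame in canonical column order.
#' @export
read_table <- function(path, schema) {
  cols <- .schemas[[match.arg(schema, names(.schemas))]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(cols, names(df))
  if (length(missing)) stop("missing required columns in ", path, ": ",
                            paste(missing, collapse = ", "))
  extra <- setdiff(names(df), cols)
  if (length(extra)) stop("unknown columns in ", path, ": ",
                          paste(extra, collapse = ", "))
  df[, cols, drop = FALSE]
}

# deterministic FNV-1a hash of an R object (for run manifests)
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' @param groups Named list of [world_config()]s, one per group arm
#'   (e.g. `list(wt = world_preset("wt_tb"), app = world_preset("app_tb"))`).
#' @param out_dir Output directory for stage CSVs and the manifest.
#' @param seed Root seed; per-group seeds derive from it deterministically.
#' @param use_images If `TRUE`, render stacks and run detection/tracing; if
#'   `FALSE` (default), drive tracking from ground-truth observation tables.
#' @param render A [render_config()] (only used with `use_images = TRUE`).
#' @param detection A [detection_params()].
#' @param tol_um Cross-session matching tolerance (um).
#' @param alpha Familywise alpha for the inference battery.
#' @param bonferroni_m Family size for post-stimulation comparisons.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(groups, out_dir = tempfile("boutondyn_run_"),
                            seed = 1L, use_images = FALSE,
                            render = render_config(),
                            detection = detection_params(),
                            tol_um = 2, alpha = 0.05, bonferroni_m = 4) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  for (g in groups) validate_world_config(g)
  structure(list(groups = groups, out_dir = out_dir, seed = as.integer(seed),
                 use_images = isTRUE(use_images), render = render,
                 detection = detection, tol_um = tol_um, alpha = alpha,
                 bonferroni_m = bonferroni_m),
            class = "pipeline_config")
}

#' Run the full bouton-dynamics pipeline
#'
#' Stages: simulate ground-truth worlds per group; either emit truth
#' observation tables directly or render per-session stacks and run
#' tracing + detection on them; build and classify tracks; compute densities
#' and interval dynamics; run the inference battery.  All stage outputs are
#' written as schema-validated CSVs under `out_dir`, with a JSON run
#' manifest (config hash, seed, per-stage row counts).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with all stage tables (`observations`,
#'   `tracks`, `axons`, `density`, `intervals`, `results`) and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)
  group_seeds <- sample.int(.Machine$integer.max - 1, length(config$groups))

  obs_all <- list(); axons_all <- list(); worlds_by_group <- list()
  for (gi in seq_along(config$groups)) {
    gname <- names(config$groups)[gi]
    cfg <- config$groups[[gi]]
    worlds <- generate_worlds(cfg, seed = group_seeds[gi])
    worlds_by_group[[gname]] <- worlds
    axons_all[[gname]] <- data.frame(
      axon_id = vapply(worlds, `[[`, "", "axon_id"),
      group = gname, type = cfg$bouton_type,
      length_um = vapply(worlds, `[[`, 0, "length_um"),
      stringsAsFactors = FALSE)
    if (config$use_images) {
      obs_g <- list()
      for (w in worlds) {
        for (s in seq_len(w$n_sessions)) {
          stk <- render_stack(w, s, config$render,
                              seed = (group_seeds[gi] + 1000L * s) %% .Machine$integer.max)
          seeds <- rbind(w$backbone[1, ], w$backbone[nrow(w$backbone), ]) -
            rep(stk$origin, each = 2)
          tr <- trace_backbone(stk, seeds)
          obs_g[[length(obs_g) + 1]] <-
            detect_boutons(stk, tr, w$bouton_type, config$detection)
        }
      }
      obs_all[[gname]] <- do.call(rbind, obs_g)
    } else {
      obs_all[[gname]] <- truth_observations(worlds)
    }
    say("simulate[%s]: %d axons, %d observations", gname,
        length(worlds), nrow(obs_all[[gname]]))
  }
  observations <- do.call(rbind, obs_all)
  rownames(observations) <- NULL
  axons <- do.call(rbind, axons_all)
  rownames(axons) <- NULL

  n_sessions <- config$groups[[1]]$n_sessions
  days <- session_days(config$groups[[1]])
  tracks <- classify_presence(
    build_tracks(observations, n_sessions, config$tol_um),
    config$detection)
  say("track: %d tracks", length(unique(tracks$track_id)))

  lengths_um <- stats::setNames(axons$length_um, axons$axon_id)
  dyn <- axon_dynamics(tracks, lengths_um, n_sessions, days)
  aux <- axons[match(dyn$density$axon_id, axons$axon_id), c("group", "type")]
  density <- cbind(dyn$density, aux)
  aux2 <- axons[match(dyn$intervals$axon_id, axons$axon_id), c("group", "type")]
  intervals <- cbind(dyn$intervals, aux2)
  say("dynamics: %d density rows, %d interval rows", nrow(density), nrow(intervals))

  results <- stats_battery(density, intervals,
                           stim_session = config$groups[[1]]$stim_session,
                           alpha = config$alpha, m = config$bonferroni_m)
  say("stats: %d result rows", nrow(results))

  write_table(observations, file.path(config$out_dir, "observations.csv"), "observations")
  write_table(tracks, file.path(config$out_dir, "tracks.csv"), "tracks")
  write_table(axons, file.path(config$out_dir, "axons.csv"), "axons")
  write_table(density, file.path(config$out_dir, "density.csv"), "density")
  write_table(intervals, file.path(config$out_dir, "intervals.csv"), "intervals")
  write_table(results, file.path(config$out_dir, "results.csv"), "results")

  manifest <- list(
    config_hash = .config_hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    use_images = config$use_images,
    rows = list(observations = nrow(observations), tracks = nrow(tracks),
                axons = nrow(axons), density = nrow(density),
                intervals = nrow(intervals), results = nrow(results)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(observations = observations, tracks = tracks, axons = axons,
                 density = density, intervals = intervals, results = results,
                 manifest = manifest, worlds = worlds_by_group))
}

#' Per-axon baseline and post-stimulation measures from a dynamics table
#'
#' Baseline = mean over the pre-stimulation intervals (sessions up to the
#' stimulation session); post values are the individual post-stimulation
#' intervals, labelled by day.
#'
#' @param intervals Interval dynamics table (with `group`/`type` columns).
#' @param measure `"turnover"`, `"gain_frac"` or `"loss_frac"`.
#' @param stim_session Session immediately after which stimulation occurs.
#' @return List of data frames: `baseline` (axon_id, group, type, value) and
#'   `post` (axon_id, group, type, day, value).
#' @export
baseline_post_split <- function(intervals, measure = "turnover",
                                stim_session = 5) {
  pre <- intervals[intervals$session_b <= stim_session, , drop = FALSE]
  post <- intervals[intervals$session_b > stim_session, , drop = FALSE]
  base <- stats::aggregate(pre[[measure]],
                           by = pre[c("axon_id", "group", "type")],
                           FUN = function(x) baseline_average(x))
  names(base)[4] <- "value"
  post_v <- post[c("axon_id", "group", "type", "day")]
  post_v$value <- post[[measure]]
  list(baseline = base, post = post_v)
}

.res_row <- function(family, measure, comparison, test, statistic, value,
                     df = NA_real_, p = NA_real_, effect = NA_real_,
                     adj_alpha = NA_real_, signif = NA) {
  data.frame(family = family, measure = measure, comparison = comparison,
             test = test, statistic = statistic, value = value, df = df,
             p = p, effect_size = effect, adjusted_alpha = adj_alpha,
             significant = signif, stringsAsFactors = FALSE)
}

#' Group-inference battery over pipeline dynamics tables
#'
#' Per bouton type: (1) Friedman test of each measure across the
#' pre-stimulation intervals within each group; (2) Mann-Whitney U between
#' the two groups on baseline-averaged turnover/gains/losses; (3) mixed
#' ANOVA (group x session, GG-corrected) on pre-stimulation density;
#' (4) Wilcoxon signed-rank of each post-stimulation day against the
#' averaged baseline within each group, interpreted against the
#' Bonferroni-adjusted alpha.
#'
#' @param density,intervals Pipeline density and interval tables.
#' @param stim_session Stimulation session.
#' @param alpha Familywise alpha.
#' @param m Bonferroni family size for the post-day comparisons.
#' @return Results table (results schema).
#' @export
stats_battery <- function(density, intervals, stim_session = 5,
                          alpha = 0.05, m = 4) {
  out <- list()
  for (type in unique(intervals$type)) {
    iv <- intervals[intervals$type == type, , drop = FALSE]
    dv <- density[density$type == type, , drop = FALSE]
    groups <- sort(unique(iv$group))
    for (measure in c("turnover", "gain_frac", "loss_frac")) {
      sp <- baseline_post_split(iv, measure, stim_session)
      # (1) baseline stability within group (Friedman across pre intervals)
      for (g in groups) {
        pre <- iv[iv$group == g & iv$session_b <= stim_session, , drop = FALSE]
        mat <- stats::xtabs(stats::as.formula(paste(measure, "~ axon_id + session_b")),
                            data = pre)
        ok <- stats::complete.cases(matrix(mat, nrow = nrow(mat)))
        if (nrow(mat) >= 2 && ncol(mat) >= 2) {
          fr <- friedman_rank_test(matrix(mat, nrow = nrow(mat))[ok, , drop = FALSE])
          out[[length(out) + 1]] <- .res_row(
            "baseline_stability", measure, paste(type, g), "friedman",
            "chi_sq", fr$chi_sq, df = fr$df, p = fr$p)
        }
      }
      # (2) between-group baseline comparison
      if (length(groups) == 2) {
        b <- sp$baseline
        x <- b$value[b$group == groups[1]]
        y <- b$value[b$group == groups[2]]
        mw <- mann_whitney_u(x, y)
        out[[length(out) + 1]] <- .res_row(
          "baseline_group", measure,
          paste(type, paste(groups, collapse = " vs ")),
          "mann_whitney", "U", mw$U, p = mw$p, effect = mw$eta_sq)
      }
      # (4) post vs baseline within group, Bonferroni family
      for (g in groups) {
        base_g <- sp$baseline[sp$baseline$group == g, ]
        days <- sort(unique(sp$post$day[sp$post$group == g]))
        fam_p <- numeric(0); fam_rows <- list()
        for (d in days) {
          post_g <- sp$post[sp$post$group == g & sp$post$day == d, ]
          mrg <- merge(base_g, post_g, by = "axon_id")
          diffs <- mrg$value.y - mrg$value.x
          diffs <- diffs[!is.na(diffs)]
          if (length(diffs) == 0 || all(diffs == 0)) next
          ws <- wilcoxon_signed_rank(diffs)
          fam_p <- c(fam_p, ws$p)
          fam_rows[[length(fam_rows) + 1]] <- .res_row(
            "post_vs_baseline", measure, sprintf("%s %s day %+g", type, g, d),
            "wilcoxon_signed_rank", "Z", ws$Z, p = ws$p)
        }
        if (length(fam_rows)) {
          bf <- bonferroni_family(fam_p, alpha, m = m)
          for (i in seq_along(fam_rows)) {
            fam_rows[[i]]$adjusted_alpha <- bf$adjusted_alpha[i]
            fam_rows[[i]]$significant <- bf$significant[i]
            out[[length(out) + 1]] <- fam_rows[[i]]
          }
        }
      }
    }
    # (3) mixed ANOVA on pre-stimulation density
    if (length(groups) == 2) {
      pre_d <- dv[dv$session <= stim_session, , drop = FALSE]
      ma <- tryCatch(
        mixed_anova(pre_d, subject = "axon_id", between = "group",
                    within = "session", value = "density_per_um"),
        error = function(e) NULL)
      if (!is.null(ma)) {
        for (i in seq_len(nrow(ma$table))) {
          r <- ma$table[i, ]
          out[[length(out) + 1]] <- .res_row(
            "baseline_density", "density_per_um", paste(type, r$effect),
            "mixed_anova", "F", r$F, df = r$df1, p = r$p,
            effect = r$partial_eta_sq)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
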