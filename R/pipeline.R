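# End-to-end orchestration: simulate -> score -> feature-extract -> stats ->
# classify, with a JSON run manifest and hash-based stage idempotence.

stage_names <- function() {
  c("simulate", "score", "eeg_features", "ans_features", "stats", "classify")
}

#' Run the full study pipeline
#'
#' Executes the pipeline stages in dependency order on a synthetic cohort:
#'
#' 1. `simulate`: cohort panels, cognitive task logs, per-participant event
#'    timelines, raw EEG and wristband streams (for `n_physio`
#'    participants), all written as plain-text files.
#' 2. `score`: cognitive logs scored into the 18 outcome measures.
#' 3. `eeg_features` / `ans_features`: event-locked physiological features
#'    per participant and session.
#' 4. `stats`: pooled-z change tables and Bonferroni-controlled change
#'    regressions for the self-report (family 14) and cognitive (family 18)
#'    measures.
#' 5. `classify`: hierarchical nested-CV evaluation of the feature groups.
#'
#' A JSON manifest recording the package version, seed, per-stage outputs
#' and their MD5 hashes is written at the end; rerunning with unchanged
#' inputs skips completed stages (hash check) unless `overwrite = TRUE`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param cv a [cv_config()] for the classification stage.
#' @param n_physio participants with physiological recordings (default:
#'   all, capped at 86 as in the emulated two-experiment design).
#' @param physio_duration length of each simulated physiological task
#'   block, s (default 120; events beyond it are trimmed).
#' @param physio_events events per physiological task block (default 24).
#' @param stages stages to run (default: all, in order).
#' @param overwrite rerun stages whose outputs already match the manifest.
#' @return the manifest, invisibly (list).
#' @export
run_study <- function(config, out_dir,
                      cv = cv_config(model_families = "logistic_l1",
                                     seed = config$seed),
                      n_physio = NULL,
                      physio_duration = 120,
                      physio_events = 24,
                      stages = stage_names(),
                      overwrite = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  stages <- match.arg(stages, stage_names(), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    recognition = file.path(out_dir, "log_recognition.csv"),
    construal = file.path(out_dir, "log_construal.csv"),
    word_find = file.path(out_dir, "log_word_find.csv"),
    events = file.path(out_dir, "events.tsv"),
    cognitive = file.path(out_dir, "cognitive_measures.csv"),
    eeg_feat = file.path(out_dir, "eeg_features.csv"),
    ans_feat = file.path(out_dir, "ans_features.csv"),
    stats_self = file.path(out_dir, "stats_self_report.csv"),
    stats_cog = file.path(out_dir, "stats_cognitive.csv"),
    ml = file.path(out_dir, "ml_accuracy.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  manifest <- if (file.exists(paths$manifest) && !overwrite) {
    tryCatch(read_json(paths$manifest, simplifyVector = TRUE),
             error = function(e) list())
  } else list()
  manifest$package <- as.character(utils::packageVersion("affectpipe"))
  manifest$seed <- config$seed
  manifest$stages <- manifest$stages %||% list()

  n_physio <- n_physio %||% min(config$n_participants, 86L)
  n_physio <- min(n_physio, config$n_participants)

  outputs_of <- list(
    simulate = c("cohort", "recognition", "construal", "word_find", "events"),
    score = "cognitive",
    eeg_features = "eeg_feat",
    ans_features = "ans_feat",
    stats = c("stats_self", "stats_cog"),
    classify = "ml"
  )

  stage_done <- function(stage) {
    files <- unlist(paths[outputs_of[[stage]]])
    rec <- manifest$stages[[stage]]
    if (is.null(rec) || overwrite) return(FALSE)
    if (!all(file.exists(files))) return(FALSE)
    hashes <- unname(md5sum(files))
    identical(unname(unlist(rec$md5)), hashes)
  }
  record_stage <- function(stage) {
    files <- unlist(paths[outputs_of[[stage]]])
    manifest$stages[[stage]] <<- list(
      outputs = unname(files),
      md5 = unname(md5sum(files))
    )
  }
  run_stage <- function(stage, fn) {
    if (!(stage %in% stages)) return(invisible(NULL))
    if (stage_done(stage)) {
      message("stage '", stage, "' up to date; skipping")
      return(invisible(NULL))
    }
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    record_stage(stage)
  }

  physio_ids <- seq_len(n_physio)
  timeline <- NULL
  get_timeline <- function() {
    if (is.null(timeline)) {
      if (file.exists(paths$events)) {
        timeline <<- read_events_tsv(paths$events)
      } else {
        stop("events file not found: ", paths$events)
      }
    }
    timeline
  }
  get_cohort <- function() read_cohort_csv(paths$cohort)

  run_stage("simulate", function() {
    cohort <- generate_cohort(config)
    write_cohort_csv(cohort, paths$cohort)
    logs <- simulate_cognitive_logs(cohort, config)
    write.csv(logs$recognition, paths$recognition, row.names = FALSE)
    write.csv(logs$construal, paths$construal, row.names = FALSE)
    write.csv(logs$word_find, paths$word_find, row.names = FALSE)
    tl <- make_event_timeline(n_events = physio_events,
                              duration = 1, isi_range = c(2.75, 3.25),
                              start = 5, seed = config$seed)
    tl <- tl[tl$onset + tl$duration <= physio_duration - 1, ]
    write_events_tsv(tl, paths$events)
  })

  run_stage("score", function() {
    logs <- list(
      recognition = read.csv(paths$recognition, stringsAsFactors = FALSE),
      construal = read.csv(paths$construal, stringsAsFactors = FALSE),
      word_find = read.csv(paths$word_find, stringsAsFactors = FALSE)
    )
    write.csv(score_cognitive_logs(logs), paths$cognitive,
              row.names = FALSE)
  })

  run_stage("eeg_features", function() {
    tl <- get_timeline()
    cohort <- get_cohort()
    rows <- list()
    for (i in physio_ids) {
      cond <- cohort$participants$condition[i]
      for (ses in c("pre", "post")) {
        rec <- simulate_eeg(tl, config, participant = i, session = ses,
                            condition = cond, duration = physio_duration)
        clean <- preprocess_eeg(rec)
        mask <- mark_artifacts(clean)
        feats <- extract_event_features(clean, tl, mask = mask)
        v <- eeg_feature_vector(feats)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(participant_id = cohort$participants$participant_id[i],
                     session = ses, stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE)
        )
      }
    }
    write.csv(do.call(rbind, rows), paths$eeg_feat, row.names = FALSE)
  })

  run_stage("ans_features", function() {
    tl <- get_timeline()
    cohort <- get_cohort()
    rows <- list()
    for (i in physio_ids) {
      cond <- cohort$participants$condition[i]
      for (ses in c("pre", "post")) {
        st <- simulate_wristband(tl, config, participant = i,
                                 session = ses, condition = cond,
                                 duration = physio_duration)
        af <- extract_event_ans_features(st, tl,
                                         task = tl$trial_type[1],
                                         hrv_window_sec = min(
                                           64, physio_duration - 2))
        v <- ans_feature_vector(af)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(participant_id = cohort$participants$participant_id[i],
                     session = ses, stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE)
        )
      }
    }
    write.csv(do.call(rbind, rows), paths$ans_feat, row.names = FALSE)
  })

  run_stage("stats", function() {
    cohort <- get_cohort()
    ch_self <- compute_change_table(cohort)
    reg_self <- change_regressions(ch_self, family = "self_report")
    write.csv(reg_self, paths$stats_self, row.names = FALSE)

    cogm <- read.csv(paths$cognitive, stringsAsFactors = FALSE)
    cog_cohort <- measures_to_cohort(cogm, cohort)
    ch_cog <- suppressWarnings(compute_change_table(cog_cohort))
    reg_cog <- change_regressions(ch_cog, family = "cognitive")
    write.csv(reg_cog, paths$stats_cog, row.names = FALSE)
  })

  run_stage("classify", function() {
    cohort <- get_cohort()
    groups <- list(self_report = change_matrix(
      compute_change_table(cohort)))
    cogm <- read.csv(paths$cognitive, stringsAsFactors = FALSE)
    cog_cohort <- measures_to_cohort(cogm, cohort)
    groups$cognitive <- change_matrix(
      suppressWarnings(compute_change_table(cog_cohort)))
    for (nm in c("ans", "eeg")) {
      path <- if (nm == "ans") paths$ans_feat else paths$eeg_feat
      if (file.exists(path)) {
        fm <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
        wide <- feature_change_matrix(fm)
        # physiology covers a subset; align by padding with NA (dropped in CV)
        full <- matrix(NA_real_, nrow(cohort$participants), ncol(wide),
                       dimnames = list(cohort$participants$participant_id,
                                       colnames(wide)))
        full[rownames(wide), ] <- wide
        groups[[nm]] <- full
      }
    }
    labels <- cohort$participants$condition
    phys <- intersect(names(groups), c("ans", "eeg"))
    cov <- groups[c("self_report", "cognitive")]
    res <- hierarchical_evaluation(cov, labels, config = cv)
    if (length(phys) > 0) {
      ok <- stats::complete.cases(do.call(cbind, groups[phys]))
      if (sum(ok) >= 20) {
        sub <- lapply(groups, function(g) g[ok, , drop = FALSE])
        res2 <- hierarchical_evaluation(sub, labels[ok], config = cv)
        res2$combination <- paste0(res2$combination, "@physio_subset")
        res <- rbind(res, res2)
      }
    }
    write.csv(res, paths$ml, row.names = FALSE)
  })

  write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Cognitive measure table (participant_id, session, measures) -> pseudo
# cohort with pre/post matrices aligned to the given cohort's participants.
measures_to_cohort <- function(measures, cohort) {
  meas_cols <- setdiff(names(measures), c("participant_id", "session"))
  pre <- measures[measures$session == "pre", ]
  post <- measures[measures$session == "post", ]
  ord <- match(cohort$participants$participant_id, pre$participant_id)
  pre_m <- as.matrix(pre[ord, meas_cols])
  ord2 <- match(cohort$participants$participant_id, post$participant_id)
  post_m <- as.matrix(post[ord2, meas_cols])
  rownames(pre_m) <- rownames(post_m) <- cohort$participants$participant_id
  structure(
    list(participants = cohort$participants, measures = meas_cols,
         pre = pre_m, post = post_m),
    class = "cohort_table"
  )
}

change_matrix <- function(change_table) {
  meas <- attr(change_table, "measures")
  m <- as.matrix(change_table[meas])
  rownames(m) <- change_table$participant_id
  m
}

# Long physiological feature file (participant_id, session, features) ->
# post - pre change matrix.
feature_change_matrix <- function(fm) {
  cols <- setdiff(names(fm), c("participant_id", "session"))
  pre <- fm[fm$session == "pre", ]
  post <- fm[fm$session == "post", ]
  ord <- match(pre$participant_id, post$participant_id)
  out <- as.matrix(post[ord, cols]) - as.matrix(pre[cols])
  rownames(out) <- pre$participant_id
  out
}
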