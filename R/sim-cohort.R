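# Synthetic cohort: condition assignment and pre/post self-report panels.

#' Generate a synthetic study cohort
#'
#' Draws pre-test self-report panels from a correlated multivariate standard
#' normal, assigns participants to the negative (0) or positive (1) writing
#' arm, and forms post-test panels as pre + arm-specific standardized mean
#' change + correlated change noise. With the default effect table, the
#' population mean pre-to-post change of each measure in each arm equals the
#' configured standardized value.
#'
#' @param config a [sim_config()].
#' @return object of class `cohort_table`: list with `participants`
#'   (data.frame: participant_id, condition), `measures`, and numeric
#'   matrices `pre` and `post` (participants x measures).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_participants = 12, seed = 1))
#' cohort
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, stream = 1L))
  n <- config$n_participants
  eff <- config$self_report_effects
  m <- nrow(eff)
  n_pos <- max(1L, min(n - 1L, round(n * config$condition_ratio)))
  condition <- integer(n)
  condition[sample.int(n, n_pos)] <- 1L

  R <- config$measure_correlation
  pre <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = R)
  noise <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = R) * config$change_sd
  delta <- rbind(eff$negative, eff$positive)[condition + 1L, , drop = FALSE]
  post <- pre + delta + noise
  colnames(pre) <- colnames(post) <- eff$measure

  structure(
    list(
      participants = data.frame(
        participant_id = sprintf("P%03d", seq_len(n)),
        condition = condition,
        stringsAsFactors = FALSE
      ),
      measures = eff$measure,
      pre = pre,
      post = post,
      seed = config$seed
    ),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  n <- nrow(x$participants)
  cat("Synthetic cohort:", n, "participants (",
      sum(x$participants$condition == 1), "positive /",
      sum(x$participants$condition == 0), "negative arm )\n")
  cat(" ", length(x$measures), "self-report measures, pre and post panels\n")
  invisible(x)
}

#' @export
as.data.frame.cohort_table <- function(x, ...) {
  pre <- as.data.frame(x$pre)
  post <- as.data.frame(x$post)
  names(pre) <- paste0("pre_", names(pre))
  names(post) <- paste0("post_", names(post))
  cbind(x$participants, pre, post)
}

# Resolve the (negative, positive) shift for a named cognitive effect,
# returning 0 when absent. Effects apply at post-test only.
cog_effect <- function(config, name, condition, session) {
  if (session != "post" || is.null(config$cognitive_effects)) return(0)
  e <- config$cognitive_effects[[name]]
  if (is.null(e)) return(0)
  unname(e[condition + 1L])
}

#' Simulate cognitive task response logs
#'
#' Produces pre and post session logs for the three cognitive tasks of every
#' participant: a 96-word recognition log (48 old / 48 new, balanced over
#' three valences) with clicks drawn from per-valence hit and false-alarm
#' probabilities; a 6-image situation-construal log (10 items per image,
#' ratings 1-7 with reaction times); and a 9-word word-find log whose find
#' orders are a permutation of 1..9 with nondecreasing find times.
#'
#' Optional condition effects (`config$cognitive_effects`) shift the
#' generating parameters at post-test: `d_prime_<val>` shifts the probit of
#' the hit probability, `construal_rn_<val>` shifts the latent construal
#' signal, and `find_time_<val>` scales the discovery gaps.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config the same [sim_config()].
#' @return list of class `cognitive_logs` with long data.frames
#'   `recognition`, `construal` and `word_find`, each carrying
#'   `participant_id` and `session` ("pre"/"post") columns.
#' @export
simulate_cognitive_logs <- function(cohort, config) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "sim_config"))
  cp <- config$cognitive
  valences <- c("pos", "neg", "neu")
  img_val <- c("pos", "neg", "amb")
  rec <- list(); con <- list(); wf <- list()
  k <- 1L
  for (i in seq_len(nrow(cohort$participants))) {
    pid <- cohort$participants$participant_id[i]
    cond <- cohort$participants$condition[i]
    for (session in c("pre", "post")) {
      set.seed(derive_seed(config$seed, i, session, stream = 2L))

      # --- recognition ---------------------------------------------------
      hit <- vapply(valences, function(v) {
        p <- cp$hit_prob[[v]]
        shift <- cog_effect(config, paste0("d_prime_", v), cond, session)
        if (shift != 0 && p > 0 && p < 1) p <- pnorm(qnorm(p) + shift)
        p
      }, numeric(1))
      fa <- cp$fa_prob[valences]
      n_cell <- cp$n_per_cell
      ent <- expand.grid(valence = valences,
                         idx = seq_len(n_cell),
                         is_old = c(TRUE, FALSE),
                         KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
      p_click <- ifelse(ent$is_old, hit[ent$valence], fa[ent$valence])
      rec[[k]] <- data.frame(
        participant_id = pid, session = session,
        word_id = sprintf("%s_w%s%02d", session,
                          ifelse(ent$is_old, "o", "n"), ent$idx),
        valence = ent$valence,
        is_old = ent$is_old,
        clicked = runif(nrow(ent)) < p_click,
        stringsAsFactors = FALSE
      )

      # --- situation construal -------------------------------------------
      images <- data.frame(
        image_id = sprintf("%s_img%d", session, 1:6),
        image_valence = rep(img_val, each = 2),
        stringsAsFactors = FALSE
      )
      rows <- images[rep(seq_len(6), each = 10), ]
      rows$item_polarity <- rep(rep(c("positive", "negative"), each = 5), 6)
      strength <- cp$construal_strength[rows$image_valence] +
        vapply(rows$image_valence,
               function(v) cog_effect(config, paste0("construal_rn_", v),
                                      cond, session),
               numeric(1))
      sign <- ifelse(rows$item_polarity == "positive", 1, -1)
      latent <- 4 + 3 * strength * sign + rnorm(nrow(rows), 0, cp$construal_sd)
      rows$rating <- as.integer(clamp(round(latent), 1, 7))
      rows$reaction_time <- rlnorm(nrow(rows), cp$rt_meanlog, cp$rt_sdlog)
      rownames(rows) <- NULL
      con[[k]] <- cbind(participant_id = pid, session = session, rows,
                        stringsAsFactors = FALSE)

      # --- word find ------------------------------------------------------
      words <- data.frame(
        word_id = sprintf("%s_find%d", session, 1:9),
        valence = rep(valences, each = 3),
        stringsAsFactors = FALSE
      )
      order_found <- sample.int(9)
      gaps <- rexp(9, rate = 1 / cp$find_gap_mean)
      scale <- vapply(words$valence[order(order_found)], function(v) {
        exp(cog_effect(config, paste0("find_time_", v), cond, session))
      }, numeric(1))
      times_sorted <- cumsum(gaps * scale) * 1000 # ms
      words$find_order <- order_found
      words$find_time <- times_sorted[order_found]
      wf[[k]] <- cbind(participant_id = pid, session = session, words,
                       stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  structure(
    list(
      recognition = do.call(rbind, rec),
      construal = do.call(rbind, con),
      word_find = do.call(rbind, wf)
    ),
    class = "cognitive_logs"
  )
}

#' @export
print.cognitive_logs <- function(x, ...) {
  cat("Cognitive task logs:\n")
  cat("  recognition:", nrow(x$recognition), "word entries\n")
  cat("  construal:  ", nrow(x$construal), "item ratings\n")
  cat("  word find:  ", nrow(x$word_find), "entries\n")
  invisible(x)
}
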