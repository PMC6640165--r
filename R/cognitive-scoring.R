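# Scoring of the three cognitive tasks into 18 outcome measures:
# 6 recognition (d-prime + criterion per valence), 6 construal, 6 word-find.

#' Score recognition memory with signal detection theory
#'
#' Computes, per word valence, the hit rate H (old words clicked), the
#' false-alarm rate F (new words clicked), and the signal-detection measures
#' d' = z(H) - z(F) and C = -(z(H) + z(F)) / 2 via the probit transform.
#' Larger d' indicates better old/new discrimination; positive C indicates a
#' conservative bias toward responding "new".
#'
#' Rates of exactly 0 or 1 make the probit infinite. Under the default
#' `correction = "rate"` they are replaced by 1/(2N) and 1 - 1/(2N), N being
#' the number of old (or new) words in the valence cell. The alternative
#' `correction = "dprime"` instead leaves the rates and sets d' itself to
#' 1/(2N) (rate 0) or 1 - 1/(2N) (rate 1), with C at 0.
#'
#' @param log data.frame with columns `valence`, `is_old` (logical),
#'   `clicked` (logical); one row per presented word.
#' @param correction boundary-rate handling, see Details.
#' @return data.frame: one row per valence with `n_old`, `n_new`,
#'   `hit_rate`, `fa_rate` (corrected), `d_prime`, `c`.
#' @export
#' @examples
#' log <- data.frame(
#'   valence = "pos",
#'   is_old = rep(c(TRUE, FALSE), each = 16),
#'   clicked = c(rep(TRUE, 12), rep(FALSE, 4), rep(TRUE, 4), rep(FALSE, 12))
#' )
#' score_recognition(log) # d' = 2 * qnorm(0.75), c = 0
score_recognition <- function(log, correction = c("rate", "dprime")) {
  correction <- match.arg(correction)
  stopifnot(all(c("valence", "is_old", "clicked") %in% names(log)))
  res <- lapply(unique(log$valence), function(v) {
    sub <- log[log$valence == v, ]
    n_old <- sum(sub$is_old)
    n_new <- sum(!sub$is_old)
    if (n_old == 0 || n_new == 0) {
      stop("empty old/new cell for valence '", v, "'")
    }
    H <- sum(sub$clicked & sub$is_old) / n_old
    F <- sum(sub$clicked & !sub$is_old) / n_new
    if (correction == "rate") {
      Hc <- clamp(H, 1 / (2 * n_old), 1 - 1 / (2 * n_old))
      Fc <- clamp(F, 1 / (2 * n_new), 1 - 1 / (2 * n_new))
      d <- qnorm(Hc) - qnorm(Fc)
      cc <- -(qnorm(Hc) + qnorm(Fc)) / 2
    } else {
      Hc <- H; Fc <- F
      if (H %in% c(0, 1) || F %in% c(0, 1)) {
        d <- if (H == 1 || F == 1) 1 - 1 / (2 * n_old) else 1 / (2 * n_old)
        cc <- 0
      } else {
        d <- qnorm(H) - qnorm(F)
        cc <- -(qnorm(H) + qnorm(F)) / 2
      }
    }
    data.frame(valence = v, n_old = n_old, n_new = n_new,
               hit_rate = Hc, fa_rate = Fc, d_prime = d, c = cc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Score the situation construal task
#'
#' Each 1-7 rating is mapped linearly onto (-1, +1) via (r - 4) / 3;
#' negative-polarity items are sign-flipped so that values above zero always
#' denote a positive appraisal of the situation. The normalized responses and
#' the reaction times are then averaged within image valence.
#'
#' @param log data.frame with columns `image_valence`, `item_polarity`
#'   ("positive"/"negative"), `rating` (integer 1-7), `reaction_time` (s).
#' @return data.frame: one row per image valence with `response_normalized`
#'   (in \[-1, 1\]) and `mean_reaction_time`.
#' @export
score_construal <- function(log) {
  stopifnot(all(c("image_valence", "item_polarity", "rating",
                  "reaction_time") %in% names(log)))
  if (any(log$rating < 1 | log$rating > 7 | log$rating != round(log$rating))) {
    stop("ratings must be integers in 1..7")
  }
  if (any(log$reaction_time <= 0)) stop("reaction times must be positive")
  rn <- (log$rating - 4) / 3
  rn[log$item_polarity == "negative"] <- -rn[log$item_polarity == "negative"]
  res <- lapply(unique(log$image_valence), function(v) {
    sel <- log$image_valence == v
    data.frame(image_valence = v,
               response_normalized = mean(rn[sel]),
               mean_reaction_time = mean(log$reaction_time[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Score the word-find task
#'
#' For each word valence group, the average of the find orders (1 = first
#' word found, 9 = last; grand mean always 5 when all nine words are found)
#' and the average time from task start to finding the words (ms).
#'
#' @param log data.frame with columns `valence`, `find_order`, `find_time`
#'   (ms). `find_order` must be a permutation of 1..n over found words.
#' @param mode `"strict"` errors when any of the 9 words is missing,
#'   listing them; `"lenient"` returns NaN for affected valence groups and
#'   attaches an `incomplete` attribute.
#' @param n_words expected word count (9 in the source design).
#' @return data.frame: one row per valence with `average_order` and
#'   `average_find_time`.
#' @export
score_word_find <- function(log, mode = c("strict", "lenient"), n_words = 9) {
  mode <- match.arg(mode)
  stopifnot(all(c("valence", "find_order", "find_time") %in% names(log)))
  found <- log[!is.na(log$find_order), ]
  if (!all(sort(found$find_order) == seq_len(nrow(found)))) {
    stop("find_order must be a permutation of 1..", nrow(found),
         " over found words")
  }
  missing_n <- n_words - nrow(found)
  incomplete <- character(0)
  if (missing_n > 0) {
    miss_ids <- if ("word_id" %in% names(log)) {
      log$word_id[is.na(log$find_order)]
    } else {
      paste0("(", missing_n, " unfound)")
    }
    if (mode == "strict") {
      stop("not all ", n_words, " words were found; missing: ",
           paste(miss_ids, collapse = ", "))
    }
    incomplete <- unique(log$valence[is.na(log$find_order)])
  }
  res <- lapply(unique(log$valence), function(v) {
    sel <- found$valence == v
    all_v <- log$valence == v
    if (v %in% incomplete || !any(sel)) {
      data.frame(valence = v, average_order = NaN,
                 average_find_time = NaN, stringsAsFactors = FALSE)
    } else {
      data.frame(valence = v,
                 average_order = mean(found$find_order[sel]),
                 average_find_time = mean(found$find_time[sel]),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  attr(out, "incomplete") <- incomplete
  out
}

#' Score all cognitive logs into the 18 outcome measures
#'
#' Applies [score_recognition()], [score_construal()] and
#' [score_word_find()] per participant and session and assembles the wide
#' 18-column measure table: `d_prime_*` and `criterion_*` for word valences
#' pos/neg/neu, `construal_rn_*` and `construal_rt_*` for image valences
#' pos/neg/amb, `find_order_*` and `find_time_*` for word valences.
#'
#' @param logs a [simulate_cognitive_logs()] result (or equivalently
#'   structured list of long data.frames).
#' @param mode word-find completeness handling, see [score_word_find()].
#' @return data.frame with `participant_id`, `session` and 18 measure
#'   columns.
#' @export
score_cognitive_logs <- function(logs, mode = "strict") {
  keys <- unique(logs$recognition[c("participant_id", "session")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    pid <- keys$participant_id[i]; ses <- keys$session[i]
    pick <- function(df) df[df$participant_id == pid & df$session == ses, ]
    sdt <- score_recognition(pick(logs$recognition))
    con <- score_construal(pick(logs$construal))
    wf <- score_word_find(pick(logs$word_find), mode = mode)
    out <- data.frame(participant_id = pid, session = ses,
                      stringsAsFactors = FALSE)
    for (v in c("pos", "neg", "neu")) {
      out[[paste0("d_prime_", v)]] <- sdt$d_prime[sdt$valence == v]
      out[[paste0("criterion_", v)]] <- sdt$c[sdt$valence == v]
    }
    for (v in c("pos", "neg", "amb")) {
      out[[paste0("construal_rn_", v)]] <-
        con$response_normalized[con$image_valence == v]
      out[[paste0("construal_rt_", v)]] <-
        con$mean_reaction_time[con$image_valence == v]
    }
    for (v in c("pos", "neg", "neu")) {
      out[[paste0("find_order_", v)]] <- wf$average_order[wf$valence == v]
      out[[paste0("find_time_", v)]] <- wf$average_find_time[wf$valence == v]
    }
    out
  })
  do.call(rbind, rows)
}
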