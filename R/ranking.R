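# CASP-style evaluation: modified ranking loss (with a uniqueness rule for
# the predictor's top pick) and NDCG@3, plus per-predictor leaderboards.

#' Modified ranking loss for one target and predictor
#'
#' The ranking loss is the true quality of the genuinely best model minus
#' the true quality of the model the predictor ranks first. A predictor's
#' top pick is only accepted when its predicted score is unique among the
#' predictor's scores for the target; otherwise the prediction is ignored
#' and the loss recorded as the sentinel 0.1 (treated as "not less than
#' 0.1").
#'
#' @param predicted predictor's scores for the target's models
#' @param true matching true quality scores
#' @param sentinel loss recorded for non-unique top picks (default 0.1)
#' @return list with `loss` and `unique_top`
#' @export
ranking_loss <- function(predicted, true, sentinel = 0.1) {
  stopifnot(length(predicted) == length(true), length(true) >= 1L)
  if (anyNA(true)) stop("missing true score for a predicted model")
  mx <- max(predicted)
  if (sum(predicted == mx) != 1L) {
    return(list(loss = sentinel, unique_top = FALSE))
  }
  list(loss = max(true) - true[which.max(predicted)], unique_top = TRUE)
}

#' Relevance of a ranked model
#'
#' One minus the squared difference between the true score of the target's
#' best model and the model's own true score; zero when the model's true
#' quality value is not unique within the target.
#'
#' @param true_best true score of the target's best model
#' @param true_i true score(s) of the ranked model(s)
#' @param unique_i logical: is the model's true quality value unique?
#' @return relevance value(s) in [0, 1]
#' @export
relevance <- function(true_best, true_i, unique_i = TRUE) {
  ifelse(unique_i, 1 - (true_best - true_i)^2, 0)
}

# DCG@3 of the ranking given by `ord` (indices into true scores).
dcg3 <- function(true, ord, unique_mask) {
  k <- min(3L, length(ord))
  i <- seq_len(k)
  r <- relevance(max(true), true[ord[i]], unique_mask[ord[i]])
  sum(r / log2(i + 1))
}

#' NDCG@3 of a predictor's ranking
#'
#' DCG@3 of the predictor's top three (relevance from [relevance()],
#' discount `1/log2(i+1)`) normalised by the DCG@3 of the true ranking,
#' so a perfect ranking scores exactly 1 when true scores are unique.
#' Targets with fewer than three models sum over the available positions.
#' Ties (in predicted or true scores) are broken by model id, so the
#' ranking is deterministic.
#'
#' @param predicted predictor's scores
#' @param true matching true scores
#' @param model_id optional model identifiers for tie-breaking
#' @return NDCG@3 in [0, 1] (NA when the ideal DCG is zero, i.e. no model
#'   has a unique true score)
#' @export
ndcg3 <- function(predicted, true, model_id = seq_along(true)) {
  stopifnot(length(predicted) == length(true))
  if (anyNA(true)) stop("missing true score for a predicted model")
  unique_mask <- !(duplicated(true) | duplicated(true, fromLast = TRUE))
  ord_pred <- order(-predicted, model_id)
  ord_true <- order(-true, model_id)
  ideal <- dcg3(true, ord_true, unique_mask)
  if (ideal == 0) return(NA_real_)
  dcg3(true, ord_pred, unique_mask) / ideal
}

#' Per-target, per-predictor ranking results
#'
#' @param predictions data.frame with columns `target_id`, `predictor`,
#'   `model_id`, `predicted_score`
#' @param truths data.frame with columns `target_id`, `model_id`,
#'   `true_score`
#' @param sentinel loss sentinel for non-unique top picks
#' @return data.frame with columns `target_id`, `predictor`, `loss`,
#'   `unique_top`, `ndcg3`
#' @export
ranking_results <- function(predictions, truths, sentinel = 0.1) {
  need_p <- c("target_id", "predictor", "model_id", "predicted_score")
  need_t <- c("target_id", "model_id", "true_score")
  if (!all(need_p %in% names(predictions))) {
    stop("predictions need columns: ", paste(need_p, collapse = ", "))
  }
  if (!all(need_t %in% names(truths))) {
    stop("truths need columns: ", paste(need_t, collapse = ", "))
  }
  out <- list()
  for (tg in unique(predictions$target_id)) {
    tt <- truths[truths$target_id == tg, ]
    pp <- predictions[predictions$target_id == tg, ]
    for (pr in unique(pp$predictor)) {
      pi <- pp[pp$predictor == pr, ]
      tr <- tt$true_score[match(pi$model_id, tt$model_id)]
      if (anyNA(tr)) {
        stop("missing truth for target ", tg, ", model(s): ",
             paste(pi$model_id[is.na(tr)], collapse = ", "))
      }
      rl <- ranking_loss(pi$predicted_score, tr, sentinel)
      out[[length(out) + 1L]] <- data.frame(
        target_id = tg, predictor = pr, loss = rl$loss,
        unique_top = rl$unique_top,
        ndcg3 = ndcg3(pi$predicted_score, tr, pi$model_id))
    }
  }
  do.call(rbind, out)
}

#' Predictor leaderboard
#'
#' Aggregates [ranking_results()] per predictor: mean ranking loss (with
#' sentinels included), the number of targets with loss below the
#' sentinel, and the summed NDCG@3. A predictor absent from a target is
#' charged the sentinel loss and zero NDCG for that target.
#'
#' @inheritParams ranking_results
#' @param metric ordering key: `"loss"` (ascending mean loss) or
#'   `"ndcg3"` (descending NDCG sum)
#' @return data.frame, one row per predictor, ordered by `metric`
#' @export
leaderboard <- function(predictions, truths, metric = c("loss", "ndcg3"),
                        sentinel = 0.1) {
  metric <- match.arg(metric)
  res <- ranking_results(predictions, truths, sentinel)
  targets <- unique(predictions$target_id)
  preds <- unique(predictions$predictor)
  rows <- lapply(preds, function(pr) {
    rp <- res[res$predictor == pr, ]
    n_missing <- length(targets) - nrow(rp)
    losses <- c(rp$loss, rep(sentinel, n_missing))
    ndcgs <- c(ifelse(is.na(rp$ndcg3), 0, rp$ndcg3), rep(0, n_missing))
    data.frame(predictor = pr,
               n_targets = length(targets),
               mean_loss = mean(losses),
               n_loss_below_sentinel = sum(losses < sentinel),
               ndcg3_sum = sum(ndcgs))
  })
  out <- do.call(rbind, rows)
  out <- if (metric == "loss") out[order(out$mean_loss), ] else
    out[order(-out$ndcg3_sum), ]
  rownames(out) <- NULL
  out
}
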