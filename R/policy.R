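#' Filtering policy
#'
#' Configures how suspicious samples are treated once the warm-up epochs
#' have passed.
#'
#' In `discard` mode a sample is removed when the abstain condition holds
#' and (with `require_correct = TRUE`, the default there) the sample is
#' currently classified correctly — the literal two-case filter rule, which
#' targets samples the model "gets right" only at an abnormal loss. With
#' `require_correct = FALSE` any sample meeting the loss condition is
#' removed. In `flip` mode a sample meeting the loss condition while
#' *misclassified* has its training label replaced by the model's current
#' prediction (flipping a correctly classified sample would be a no-op, so
#' `require_correct` is forced off there).
#'
#' @param alpha Positive multiplier on the class average loss; larger is
#'   more conservative (default 1).
#' @param mode `"discard"` or `"flip"`.
#' @param warmup_epochs Number of initial epochs during which statistics
#'   accumulate but nothing is filtered (default 2).
#' @param require_correct Whether the condition additionally requires
#'   `y == y_hat`; defaults to `TRUE` in discard mode, `FALSE` in flip mode.
#' @param tracker_scope `"per_class"` or `"global"`.
#' @param enabled Set `FALSE` for a plain baseline run (no tracker-driven
#'   actions at any epoch).
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(alpha = 1, mode = c("discard", "flip"),
                          warmup_epochs = 2L, require_correct = NULL,
                          tracker_scope = c("per_class", "global"),
                          enabled = TRUE) {
  mode <- match.arg(mode)
  tracker_scope <- match.arg(tracker_scope)
  if (alpha <= 0) stopf("alpha must be > 0")
  if (warmup_epochs < 0) stopf("warmup_epochs must be >= 0")
  if (is.null(require_correct)) require_correct <- (mode == "discard")
  if (mode == "flip") require_correct <- FALSE
  structure(list(alpha = alpha, mode = mode,
                 warmup_epochs = as.integer(warmup_epochs),
                 require_correct = isTRUE(require_correct),
                 tracker_scope = tracker_scope, enabled = isTRUE(enabled)),
            class = "filter_policy")
}

#' The abstain condition
#'
#' `TRUE` when `loss >= alpha * class_avg` (boundary inclusive). An `NA`
#' class average (no statistics yet) never triggers.
#'
#' @param loss Nonnegative loss value(s).
#' @param class_avg Running class average(s); may be `NA`.
#' @param alpha Positive multiplier.
#' @return Logical vector.
#' @export
abstain_condition <- function(loss, class_avg, alpha) {
  if (any(loss < 0, na.rm = TRUE)) stopf("losses must be nonnegative")
  if (alpha <= 0) stopf("alpha must be > 0")
  !is.na(class_avg) & loss >= alpha * class_avg
}

#' Decide actions for one batch
#'
#' Applies the policy to each sample against the tracker state *before*
#' this batch is recorded, so a sample's own loss never inflates the
#' threshold it is judged by.
#'
#' @param outcome A [batch_outcome()].
#' @param tracker A `loss_tracker` (pre-batch state).
#' @param policy A [filter_policy()].
#' @param epoch,iteration Bookkeeping fields copied into the decisions.
#' @return Data frame of decisions: `epoch`, `iteration`, `patch_id`,
#'   `loss`, `class_average`, `alpha`, `correct`, `action`
#'   (`"keep"`/`"discard"`/`"flip"`), `new_label` (`NA` unless flipping).
#' @export
filter_batch <- function(outcome, tracker, policy, epoch = NA_integer_,
                         iteration = NA_integer_) {
  stopifnot(inherits(policy, "filter_policy"))
  avg <- vapply(outcome$y, function(cl) class_average(tracker, cl), numeric(1))
  hot <- abstain_condition(outcome$loss, avg, policy$alpha)
  action <- rep("keep", nrow(outcome))
  new_label <- rep(NA_integer_, nrow(outcome))
  if (policy$mode == "discard") {
    act <- hot & (!policy$require_correct | outcome$correct)
    action[act] <- "discard"
  } else {
    act <- hot & !outcome$correct
    action[act] <- "flip"
    new_label[act] <- outcome$y_hat[act]
  }
  data.frame(epoch = epoch, iteration = iteration,
             patch_id = outcome$patch_id, loss = outcome$loss,
             class_average = avg, alpha = policy$alpha,
             correct = outcome$correct, action = action,
             new_label = new_label, stringsAsFactors = FALSE)
}

#' Apply filter decisions to a manifest
#'
#' Discards remove training records permanently; flips overwrite the
#' record's training label (updating the `is_noisy` flag against any known
#' clean label). A discard decision for a record that is already gone is a
#' stale no-op, marked in the returned log. Decisions touching validation
#' or test records are a hard error.
#'
#' @param manifest A `patch_manifest`.
#' @param decisions Decisions from [filter_batch()].
#' @param mode `"discard"` or `"flip"` (must match the decisions' actions).
#' @return List with `manifest` (updated) and `log` (the non-keep decisions
#'   with an added logical `stale` column).
#' @export
apply_decisions <- function(manifest, decisions, mode = c("discard", "flip")) {
  mode <- match.arg(mode)
  acts <- decisions[decisions$action != "keep", , drop = FALSE]
  r <- manifest$records
  if (!nrow(acts))
    return(list(manifest = manifest,
                log = cbind(acts, stale = logical(0))))
  idx <- match(acts$patch_id, r$patch_id)
  present <- !is.na(idx)
  if (any(present)) {
    sp <- r$split[idx[present]]
    if (any(sp != "train"))
      stopf("filter decision targets non-train patch '%s'",
            acts$patch_id[present][sp != "train"][1])
  }
  stale <- !present
  if (mode == "discard") {
    drop_idx <- idx[present & acts$action == "discard"]
    if (length(drop_idx)) r <- r[-drop_idx, , drop = FALSE]
  } else {
    fl <- present & acts$action == "flip"
    if (any(fl)) {
      r$label[idx[fl]] <- acts$new_label[fl]
      known <- !is.na(r$clean_label[idx[fl]])
      r$is_noisy[idx[fl]][known] <-
        r$clean_label[idx[fl]][known] != r$label[idx[fl]][known]
    }
  }
  rownames(r) <- NULL
  list(manifest = patch_manifest(r, manifest$classes, manifest$provenance),
       log = cbind(acts, stale = stale))
}

empty_decisions <- function() {
  data.frame(epoch = integer(0), iteration = integer(0),
             patch_id = character(0), loss = numeric(0),
             class_average = numeric(0), alpha = numeric(0),
             correct = logical(0), action = character(0),
             new_label = integer(0), stale = logical(0),
             stringsAsFactors = FALSE)
}

#' Write a decision log as JSON lines
#'
#' One JSON object per non-keep decision, in order.
#'
#' @param decisions Decision data frame (e.g. `fit$decisions`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decision_log <- function(decisions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(decisions)) {
    for (i in seq_len(nrow(decisions))) {
      writeLines(jsonlite::toJSON(as.list(decisions[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA, na = "null"),
                 con)
    }
  }
  invisible(path)
}

#' Read a JSON-lines decision log
#'
#' @param path Path written by [write_decision_log()].
#' @return Decision data frame.
#' @export
read_decision_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(epoch = integer(0), iteration = integer(0),
                      patch_id = character(0), loss = numeric(0),
                      class_average = numeric(0), alpha = numeric(0),
                      correct = logical(0), action = character(0),
                      new_label = integer(0), stale = logical(0)))
  }
  do.call(rbind, lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    o$new_label <- if (is.null(o$new_label)) NA_integer_ else as.integer(o$new_label)
    as.data.frame(o, stringsAsFactors = FALSE)
  }))
}
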