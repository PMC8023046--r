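# Gold-standard consensus over specialist triples with expert adjudication.
#
# Each recording is labelled independently by three specialists, any of whom
# may mark it indeterminate (unable to distinguish). The decision rules:
#   - all three agree on a non-indeterminate label  -> accepted (unanimous)
#   - two or more indeterminate                     -> rejected
#   - exactly two agree on a non-indeterminate label -> expert adjudication
#   - otherwise (no two agree)                       -> rejected
# Whether a (X, X, indeterminate) triple goes to adjudication or is rejected
# is a policy switch; the default routes it to the expert group, since only a
# fully consistent triple qualifies directly. Rater identities never enter
# the rules (raters are anonymous at this layer).

#' Decide one specialist triple
#'
#' @param labels character vector of exactly three labels from
#'   `crackle`/`wheeze`/`normal`/`indeterminate`.
#' @param indeterminate_pair_policy what to do with a (X, X, indeterminate)
#'   triple: `"adjudicate"` (default) sends it to the expert group,
#'   `"reject"` drops it.
#' @return a `gs_decision`: list with `status` (`accepted`, `rejected`,
#'   `needs_adjudication`), `label` (`NA` unless accepted), `provenance`
#'   (`unanimous` or `NA`) and `rule` (which rule fired).
#' @export
specialist_round <- function(labels,
                             indeterminate_pair_policy = c("adjudicate",
                                                           "reject")) {
  policy <- match.arg(indeterminate_pair_policy)
  if (length(labels) != 3) stop("a specialist triple has exactly 3 labels")
  bad <- setdiff(labels, RATER_LABELS)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  n_ind <- sum(labels == "indeterminate")
  non_ind <- labels[labels != "indeterminate"]

  if (n_ind == 0 && length(unique(labels)) == 1)
    return(gs_decision("accepted", labels[1], "unanimous", "unanimous"))
  if (n_ind >= 2)
    return(gs_decision("rejected", NA, NA, "majority_indeterminate"))
  pair <- names(which(table(non_ind) == 2))
  if (length(pair) == 1) {
    if (n_ind == 1 && policy == "reject")
      return(gs_decision("rejected", NA, NA, "indeterminate_pair"))
    return(gs_decision("needs_adjudication", NA, NA,
                       if (n_ind == 1) "pair_vs_indeterminate"
                       else "pair_vs_dissent"))
  }
  gs_decision("rejected", NA, NA, "inconsistent")
}

gs_decision <- function(status, label, provenance, rule) {
  structure(list(status = status, label = label, provenance = provenance,
                 rule = rule),
            class = "gs_decision")
}

#' @export
print.gs_decision <- function(x, ...) {
  cat(sprintf("<gs_decision: %s%s (%s)>\n", x$status,
              if (!is.na(x$label)) paste0(" ", x$label) else "", x$rule))
  invisible(x)
}

#' Expert adjudication of a pending decision
#'
#' @param decision a `gs_decision` with status `needs_adjudication`.
#' @param expert_label the expert group's label; a non-indeterminate label
#'   accepts the recording with that label, `"indeterminate"` or `"reject"`
#'   rejects it.
#' @return the finalized `gs_decision` (`adjudicated` or `rejected`).
#' @export
adjudicate <- function(decision, expert_label) {
  stopifnot(inherits(decision, "gs_decision"))
  if (decision$status != "needs_adjudication")
    stop("adjudicate() requires a pending decision (status is '",
         decision$status, "')")
  if (expert_label %in% c("indeterminate", "reject"))
    return(gs_decision("rejected", NA, NA, "expert_reject"))
  if (!expert_label %in% BREATH_CLASSES)
    stop("unknown expert label: ", expert_label)
  gs_decision("adjudicated", expert_label, "expert", "expert_label")
}

#' Build the gold standard for a whole corpus
#'
#' @param ratings data.frame `recording_id,rater_id,label` with exactly three
#'   rows per recording.
#' @param expert_labels data.frame `recording_id,expert_label`; required for
#'   every recording whose triple needs adjudication.
#' @param indeterminate_pair_policy see [specialist_round()].
#' @return data.frame `recording_id,gs_label,status,provenance,rule` (one row
#'   per recording; `gs_label` is `NA` for rejected recordings). This table
#'   doubles as the audit log: `rule` records which decision rule fired.
#' @export
build_gold_standard <- function(ratings, expert_labels = NULL,
                                indeterminate_pair_policy = "adjudicate") {
  if (nrow(ratings) == 0)
    return(data.frame(recording_id = character(), gs_label = character(),
                      status = character(), provenance = character(),
                      rule = character()))
  counts <- table(ratings$recording_id)
  if (any(counts != 3))
    stop("expected exactly 3 ratings per recording; offending: ",
         paste(names(counts)[counts != 3], collapse = ", "))
  ids <- sort(unique(ratings$recording_id))
  decisions <- lapply(ids, function(id)
    specialist_round(ratings$label[ratings$recording_id == id],
                     indeterminate_pair_policy))
  pending <- ids[vapply(decisions, function(d)
    d$status == "needs_adjudication", logical(1))]
  if (length(pending)) {
    have <- if (is.null(expert_labels)) character() else
      expert_labels$recording_id
    missing_ids <- setdiff(pending, have)
    if (length(missing_ids))
      stop("missing expert label for pending recordings: ",
           paste(missing_ids, collapse = ", "))
    for (id in pending) {
      k <- match(id, ids)
      decisions[[k]] <- adjudicate(
        decisions[[k]],
        expert_labels$expert_label[match(id, expert_labels$recording_id)])
    }
  }
  data.frame(
    recording_id = ids,
    gs_label = vapply(decisions, function(d) as.character(d$label),
                      character(1)),
    status = vapply(decisions, function(d) d$status, character(1)),
    provenance = vapply(decisions, function(d) as.character(d$provenance),
                        character(1)),
    rule = vapply(decisions, function(d) d$rule, character(1)))
}
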