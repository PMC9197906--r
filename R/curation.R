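#' Post a curation message
#'
#' Curation messages are typed issues attached to a compound or spectrum
#' card: external-identifier conflicts detected at merge time
#' (`EXTERNAL_ID_CONFLICT`), property mismatches (`PROPERTY_MISMATCH`) and
#' free-form user reports (`USER_REPORT`). They are collected in the store's
#' message centre with an open -> resolved lifecycle.
#'
#' @param store A `pb_store`.
#' @param target pf_id of an existing compound or spectrum card.
#' @param kind One of `"EXTERNAL_ID_CONFLICT"`, `"PROPERTY_MISMATCH"`,
#'   `"USER_REPORT"`.
#' @param text Human-readable description of the issue.
#' @param author Authenticated user (or `"system"` for engine-generated
#'   conflicts).
#' @return The new message (class `curation_message`), status `"open"`.
#' @export
post_message <- function(store, target, kind = c("USER_REPORT",
                                                 "EXTERNAL_ID_CONFLICT",
                                                 "PROPERTY_MISMATCH"),
                         text, author) {
  .pb_check_store(store)
  kind <- match.arg(kind)
  if (!identical(author, "system")) {
    .pb_require_authenticated(store, author, "post curation messages")
  }
  target_kind <- if (target %in% names(store$compounds)) {
    "compound"
  } else if (target %in% names(store$spectra)) {
    "spectrum"
  } else {
    stop(sprintf("cannot post message on unknown card '%s'", target), call. = FALSE)
  }
  msg <- structure(list(
    id = .pb_next_id(store, "message"),
    target_kind = target_kind,
    target = target,
    kind = kind,
    text = text,
    author = author,
    created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = "open",
    resolved_by = NULL,
    resolution_note = NULL
  ), class = "curation_message")
  store$messages[[msg$id]] <- msg
  msg
}

#' @export
print.curation_message <- function(x, ...) {
  cat("<curation message> ", x$id, " [", x$status, "] ", x$kind,
      " on ", x$target, "\n  ", x$text, "\n", sep = "")
  invisible(x)
}

#' List curation messages
#'
#' @param store A `pb_store`.
#' @param status Optional filter: `"open"` or `"resolved"`.
#' @param kind Optional filter on message kind.
#' @param target Optional filter on the target card's pf_id.
#' @return Data frame of matching messages (zero rows when none).
#' @export
list_messages <- function(store, status = NULL, kind = NULL, target = NULL) {
  .pb_check_store(store)
  msgs <- store$messages
  keep <- vapply(msgs, function(m) {
    (is.null(status) || m$status == status) &&
      (is.null(kind) || m$kind == kind) &&
      (is.null(target) || m$target == target)
  }, logical(1))
  msgs <- msgs[keep]
  if (length(msgs) == 0) {
    return(data.frame(id = character(0), target_kind = character(0),
                      target = character(0), kind = character(0),
                      text = character(0), author = character(0),
                      created_at = character(0), status = character(0),
                      resolved_by = character(0), resolution_note = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(msgs, function(m) {
    data.frame(id = m$id, target_kind = m$target_kind, target = m$target,
               kind = m$kind, text = m$text, author = m$author,
               created_at = m$created_at, status = m$status,
               resolved_by = if (is.null(m$resolved_by)) NA_character_ else m$resolved_by,
               resolution_note = if (is.null(m$resolution_note)) NA_character_ else m$resolution_note,
               stringsAsFactors = FALSE)
  }))
}

#' Resolve a curation message
#'
#' Resolution is terminal: a message moves open -> resolved exactly once
#' and records who resolved it. Re-importing the same conflicting
#' identifier after resolution creates a fresh open message (conflicts are
#' not deduplicated).
#'
#' @param store A `pb_store`.
#' @param id Message id.
#' @param resolver Curator or admin.
#' @param note Optional resolution note.
#' @return The resolved message.
#' @export
resolve_message <- function(store, id, resolver, note = NULL) {
  .pb_check_store(store)
  .pb_require_role(store, resolver, c("curator", "admin"), "resolve messages")
  if (!id %in% names(store$messages)) {
    stop(sprintf("unknown curation message '%s'", id), call. = FALSE)
  }
  msg <- store$messages[[id]]
  if (msg$status != "open") {
    stop(sprintf("message %s is already resolved", id), call. = FALSE)
  }
  msg$status <- "resolved"
  msg$resolved_by <- resolver
  msg$resolution_note <- note
  store$messages[[id]] <- msg
  msg
}
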