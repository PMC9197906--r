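#' Create an empty spectral knowledge-base store
#'
#' The store is the in-memory database all other operations act on: a
#' compound registry keyed by InChIKey, a spectrum store, the curation
#' message centre, an audit trail and a small user/role table. It is an
#' environment, so registry operations mutate it in place and every
#' reference sees the same state.
#'
#' Three users exist by default: `"admin"` (role admin), `"curator"` (role
#' curator) and `"user"` (role user). Add more with [add_user()].
#'
#' @return An object of class `pb_store`.
#' @examples
#' store <- new_store()
#' @export
new_store <- function() {
  s <- new.env(parent = emptyenv())
  s$compounds <- list()               # pf_id -> compound card
  s$inchikey_index <- character(0)    # inchikey -> pf_id
  s$spectra <- list()                 # pf_id -> spectrum card
  s$messages <- list()                # message id -> curation message
  s$audit <- list()
  s$users <- c(admin = "admin", curator = "curator", user = "user")
  s$seq <- c(compound = 0L, spectrum = 0L, message = 0L)
  class(s) <- "pb_store"
  s
}

#' @export
print.pb_store <- function(x, ...) {
  open_msgs <- sum(vapply(x$messages, function(m) m$status == "open", logical(1)))
  cat("<pb_store> ", length(x$compounds), " compounds, ",
      length(x$spectra), " spectra, ",
      length(x$messages), " curation messages (", open_msgs, " open)\n", sep = "")
  invisible(x)
}

#' Add a user to a store
#'
#' Roles follow the usual three-tier scheme of collaborative curation
#' platforms: `user` (authenticated, may report issues and annotate),
#' `curator` (may grade, resolve and edit), `admin`.
#'
#' @param store A `pb_store`.
#' @param name Login name.
#' @param role One of `"admin"`, `"curator"`, `"user"`.
#' @return The store, invisibly.
#' @export
add_user <- function(store, name, role = c("user", "curator", "admin")) {
  .pb_check_store(store)
  role <- match.arg(role)
  store$users[[name]] <- role
  invisible(store)
}

.pb_check_store <- function(store) {
  if (!inherits(store, "pb_store")) stop("not a pb_store", call. = FALSE)
  invisible(store)
}

.pb_role <- function(store, actor) {
  if (is.null(actor) || !actor %in% names(store$users)) return(NA_character_)
  unname(store$users[[actor]])
}

.pb_require_role <- function(store, actor, roles, what) {
  role <- .pb_role(store, actor)
  if (is.na(role) || !role %in% roles) {
    cond <- structure(
      class = c("pb_permission_error", "error", "condition"),
      list(message = sprintf("actor '%s' lacks the %s role required to %s",
                             if (is.null(actor)) "<none>" else actor,
                             paste(roles, collapse = "/"), what),
           call = NULL)
    )
    stop(cond)
  }
  invisible(role)
}

.pb_require_authenticated <- function(store, actor, what) {
  if (is.null(actor) || is.na(.pb_role(store, actor))) {
    cond <- structure(
      class = c("pb_permission_error", "error", "condition"),
      list(message = sprintf("unauthenticated actor cannot %s", what), call = NULL)
    )
    stop(cond)
  }
  invisible(actor)
}

.pb_next_id <- function(store, kind = c("compound", "spectrum", "message")) {
  kind <- match.arg(kind)
  store$seq[[kind]] <- store$seq[[kind]] + 1L
  switch(kind,
    compound = sprintf("PFc%06d", store$seq[[kind]]),
    spectrum = sprintf("PFs%06d", store$seq[[kind]]),
    message = sprintf("PFm%06d", store$seq[[kind]])
  )
}

.pb_audit <- function(store, actor, action, target, from = NULL, to = NULL) {
  store$audit[[length(store$audit) + 1L]] <- list(
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    actor = actor,
    action = action,
    target = target,
    from = from,
    to = to
  )
  invisible(store)
}

#' Audit trail of a store
#'
#' @param store A `pb_store`.
#' @return Data frame with one row per recorded state transition (star
#'   grading, MSI level changes, peak annotation edits).
#' @export
audit_log <- function(store) {
  .pb_check_store(store)
  if (length(store$audit) == 0) {
    return(data.frame(time = character(0), actor = character(0),
                      action = character(0), target = character(0),
                      from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(store$audit, function(e) {
    data.frame(time = e$time, actor = e$actor, action = e$action,
               target = e$target,
               from = if (is.null(e$from)) NA_character_ else as.character(e$from),
               to = if (is.null(e$to)) NA_character_ else as.character(e$to),
               stringsAsFactors = FALSE)
  }))
}

#' Fetch a compound card
#'
#' @param store A `pb_store`.
#' @param pf_id Internal compound identifier (`PFc...`) or an InChIKey.
#' @return The compound card, or an error when unknown.
#' @export
get_compound <- function(store, pf_id) {
  .pb_check_store(store)
  if (pf_id %in% names(store$compounds)) return(store$compounds[[pf_id]])
  if (pf_id %in% names(store$inchikey_index)) {
    return(store$compounds[[store$inchikey_index[[pf_id]]]])
  }
  stop(sprintf("unknown compound '%s'", pf_id), call. = FALSE)
}

#' Fetch a spectrum card
#'
#' @param store A `pb_store`.
#' @param pf_id Internal spectrum identifier (`PFs...`).
#' @return The spectrum card.
#' @export
get_spectrum <- function(store, pf_id) {
  .pb_check_store(store)
  if (!pf_id %in% names(store$spectra)) {
    stop(sprintf("unknown spectrum '%s'", pf_id), call. = FALSE)
  }
  store$spectra[[pf_id]]
}

#' Save a store to a JSON file
#'
#' Persists the full store state (compounds, spectra, curation messages,
#' audit trail, users, id counters) with `jsonlite::serializeJSON`, which
#' preserves R types exactly, so `store_load(store_save(s))` reproduces `s`.
#'
#' @param store A `pb_store`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
store_save <- function(store, path) {
  .pb_check_store(store)
  snapshot <- list(
    format = "peakbase-store",
    version = 1L,
    compounds = store$compounds,
    inchikey_index = store$inchikey_index,
    spectra = store$spectra,
    messages = store$messages,
    audit = store$audit,
    users = store$users,
    seq = store$seq
  )
  writeLines(jsonlite::serializeJSON(snapshot, digits = 17), path)
  invisible(path)
}

#' Load a store from a JSON file
#'
#' @param path File written by [store_save()].
#' @return A `pb_store`.
#' @export
store_load <- function(path) {
  snapshot <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                              collapse = "\n"))
  if (!identical(snapshot$format, "peakbase-store")) {
    stop("not a peakbase store file: ", path, call. = FALSE)
  }
  s <- new_store()
  s$compounds <- snapshot$compounds
  s$inchikey_index <- snapshot$inchikey_index
  s$spectra <- snapshot$spectra
  s$messages <- snapshot$messages
  s$audit <- snapshot$audit
  s$users <- snapshot$users
  s$seq <- snapshot$seq
  s
}
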