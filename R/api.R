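# Canonical card -> plain-list conversions shared by the JSON API and the
# CLI --json output, so both surfaces serialize identically.

#' Convert a card to a plain list (JSON shape)
#'
#' @param card A compound or spectrum card.
#' @return A list free of S3 classes, ready for `jsonlite::toJSON`.
#' @export
card_to_list <- function(card) {
  if (inherits(card, "compound_card")) {
    list(
      kind = "compound",
      pf_id = card$pf_id,
      inchikey = card$inchikey,
      inchi = card$inchi,
      names = lapply(card$names, function(n) {
        list(text = n$text, score = n$score, is_primary = isTRUE(n$is_primary))
      }),
      formula = card$formula,
      monoisotopic_mass = card$monoisotopic_mass,
      average_mass = card$average_mass,
      canonical_smiles = card$canonical_smiles,
      cross_refs = as.list(card$cross_refs),
      publications = card$publications,
      stars = card$stars,
      elucidation = card$elucidation,
      logp = card$logp,
      endogenous_flag = card$endogenous_flag
    )
  } else if (inherits(card, "spectrum_card")) {
    list(
      kind = "spectrum",
      pf_id = card$pf_id,
      technique = card$technique,
      sample_type = card$sample_type,
      compound_links = card$compound_links,
      metadata = card$metadata,
      peaks = card$peaks,
      splash = card$splash
    )
  } else {
    stop("not a card", call. = FALSE)
  }
}

.pb_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null", dataframe = "rows")
}

.pb_openapi <- function() {
  param <- function(name, type = "string", required = TRUE) {
    list(name = name, `in` = "query", required = required,
         schema = list(type = type))
  }
  list(
    openapi = "3.0.0",
    info = list(title = "peakbase programmatic interface", version = "0.1.0"),
    paths = list(
      "/compounds/{pf_id}" = list(get = list(
        summary = "Fetch a compound card",
        parameters = list(list(name = "pf_id", `in` = "path", required = TRUE,
                               schema = list(type = "string"))))),
      "/spectra/{pf_id}" = list(get = list(
        summary = "Fetch a spectrum card",
        parameters = list(list(name = "pf_id", `in` = "path", required = TRUE,
                               schema = list(type = "string"))))),
      "/search/compounds" = list(get = list(
        summary = "Quick search over compounds",
        parameters = list(param("q")))),
      "/search/peaks" = list(get = list(
        summary = "m/z tolerance search over MS peaks",
        parameters = list(param("mz", "number"), param("tol", "number"),
                          param("unit", "string", FALSE)))),
      "/search/shifts" = list(get = list(
        summary = "Chemical-shift window search over NMR peaks",
        parameters = list(param("ppm", "number"), param("tol", "number"))))
    ),
    components = list(securitySchemes = list(
      bearer = list(type = "http", scheme = "bearer")))
  )
}

#' Handle one request of the JSON programmatic interface
#'
#' Transport-agnostic implementation of the read-only JSON interface: the
#' same handler backs [serve_api()] (HTTP via httpuv, when installed) and
#' can be driven directly in-process. Every endpoint except the interface
#' description at `/openapi.json` requires a valid bearer token; an
#' invalid or missing token yields status 401, an unknown id 404.
#'
#' @param store A `pb_store`.
#' @param path Request path, e.g. `"/compounds/PFc000001"`.
#' @param query Named list of query parameters (values as strings).
#' @param token Bearer token presented by the client, or `NULL`.
#' @param tokens Character vector of accepted tokens.
#' @return List with `status` (HTTP status code) and `body` (R object;
#'   serialize with `jsonlite::toJSON(..., auto_unbox = TRUE)`).
#' @export
api_handle <- function(store, path, query = list(), token = NULL,
                       tokens = character()) {
  .pb_check_store(store)
  if (path == "/openapi.json") {
    return(list(status = 200L, body = .pb_openapi()))
  }
  if (is.null(token) || !token %in% tokens) {
    return(list(status = 401L, body = list(error = "missing or invalid bearer token")))
  }
  not_found <- function(what) list(status = 404L, body = list(error = what))
  bad <- function(what) list(status = 400L, body = list(error = what))

  if (grepl("^/compounds/", path)) {
    id <- sub("^/compounds/", "", path)
    card <- tryCatch(get_compound(store, id), error = function(e) NULL)
    if (is.null(card)) return(not_found(sprintf("unknown compound '%s'", id)))
    return(list(status = 200L, body = card_to_list(card)))
  }
  if (grepl("^/spectra/", path)) {
    id <- sub("^/spectra/", "", path)
    card <- tryCatch(get_spectrum(store, id), error = function(e) NULL)
    if (is.null(card)) return(not_found(sprintf("unknown spectrum '%s'", id)))
    return(list(status = 200L, body = card_to_list(card)))
  }
  if (path == "/search/compounds") {
    if (is.null(query$q)) return(bad("missing query parameter 'q'"))
    hits <- quick_search(store, query$q)
    return(list(status = 200L, body = hits[hits$kind == "compound", , drop = FALSE]))
  }
  if (path == "/search/peaks") {
    if (is.null(query$mz) || is.null(query$tol)) {
      return(bad("missing query parameter 'mz' or 'tol'"))
    }
    unit <- if (is.null(query$unit)) "ppm" else query$unit
    res <- tryCatch(
      search_peaks_mz(store, as.numeric(query$mz),
                      mass_tolerance(as.numeric(query$tol), unit)),
      error = function(e) e)
    if (inherits(res, "error")) return(bad(conditionMessage(res)))
    return(list(status = 200L, body = res))
  }
  if (path == "/search/shifts") {
    if (is.null(query$ppm) || is.null(query$tol)) {
      return(bad("missing query parameter 'ppm' or 'tol'"))
    }
    res <- tryCatch(
      search_peaks_shift(store, as.numeric(query$ppm), as.numeric(query$tol)),
      error = function(e) e)
    if (inherits(res, "error")) return(bad(conditionMessage(res)))
    return(list(status = 200L, body = res))
  }
  not_found(sprintf("no such endpoint: %s", path))
}

#' Serve the JSON interface over HTTP
#'
#' Binds [api_handle()] to an HTTP port using the httpuv package (listed in
#' Suggests; serving is optional, the handler itself has no HTTP
#' dependency). Clients authenticate with `Authorization: Bearer <token>`.
#'
#' @param store A `pb_store`.
#' @param tokens Accepted bearer tokens.
#' @param host,port Bind address.
#' @return The httpuv server handle; stop it with `httpuv::stopServer()`.
#' @export
serve_api <- function(store, tokens, host = "127.0.0.1", port = 8080) {
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    stop("serving over HTTP requires the httpuv package; use api_handle() in-process instead",
         call. = FALSE)
  }
  httpuv::startServer(host, port, list(
    call = function(req) {
      auth <- req$HTTP_AUTHORIZATION
      token <- if (!is.null(auth) && grepl("^Bearer ", auth)) {
        sub("^Bearer ", "", auth)
      } else NULL
      query <- .pb_parse_query(req$QUERY_STRING)
      res <- api_handle(store, req$PATH_INFO, query, token, tokens)
      list(status = res$status,
           headers = list("Content-Type" = "application/json"),
           body = as.character(.pb_json(res$body)))
    }
  ))
}

.pb_parse_query <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  parts <- strsplit(qs, "&", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    out[[utils::URLdecode(kv[1])]] <- utils::URLdecode(paste(kv[-1], collapse = "="))
  }
  out
}
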