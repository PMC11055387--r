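# Bracket notation for proteoforms and PTM queries.
#
# Angle brackets denote an exact molecular state: <K9me2K27me1> is a molecule
# carrying exactly those marks and nothing else. Curly brackets denote a
# containment query: {K9me2} sums every proteoform carrying K9me2, whatever
# else it carries. Query tokens additionally allow disjunctions ("K9me2/3" =
# me2 or me3 at K9) and explicit absence ("K9un" = site 9 unmodified). The
# fully unmodified proteoform is written "<un>"; a fixed N-terminal
# acetylation (H4) is implied and omitted from canonical labels.

.token_rx <- "(N-ac|un|K[0-9]+(?:ac|me[1-3](?:/[1-3])*|un))"

.tokenize_notation <- function(body, where) {
  if (body == "") return(character())
  m <- gregexpr(.token_rx, body)[[1]]
  toks <- regmatches(body, gregexpr(.token_rx, body))[[1]]
  if (sum(nchar(toks)) != nchar(body)) {
    abort(paste0("malformed notation '", where, "': unparseable characters"))
  }
  toks
}

.parse_token <- function(tok) {
  if (tok == "N-ac") return(list(site = 0L, kinds = "ac"))
  if (tok == "un") return(list(site = NA_integer_, kinds = "un"))
  site <- as.integer(sub("^K([0-9]+).*$", "\\1", tok))
  rest <- sub("^K[0-9]+", "", tok)
  if (rest == "un") return(list(site = site, kinds = "un"))
  if (rest == "ac") return(list(site = site, kinds = "ac"))
  degrees <- strsplit(sub("^me", "", rest), "/")[[1]]
  list(site = site, kinds = paste0("me", degrees))
}

#' Parse bracket notation into a proteoform or PTM query
#'
#' `"<...>"` yields an exact [proteoform()]; `"{...}"` yields a containment
#' query ([ptm_query()]). Within queries, `"me2/3"` is a disjunction and
#' `"K9un"` requires the site to be unmodified. `"<un>"` is the canonical
#' label for the fully unmodified proteoform.
#'
#' @param text A single bracketed expression, e.g. `"<N-acK12acK16acK31ac>"`
#'   or `"{K9me2/3}"`.
#' @param backbone A [histone_backbone()] naming the site space.
#' @return A `proteoform` or `ptm_query` object.
#' @examples
#' h4 <- histone_backbone("H4")
#' parse_notation("<K20me2>", h4)
#' h3 <- histone_backbone("H3.2")
#' parse_notation("{K9me2/3}", h3)
#' @export
parse_notation <- function(text, backbone) {
  stopifnot(is.character(text), length(text) == 1)
  text <- gsub("[[:space:]]", "", text)
  if (grepl("^<.*>$", text)) {
    exact <- TRUE
  } else if (grepl("^\\{.*\\}$", text)) {
    exact <- FALSE
  } else {
    abort(paste0("malformed brackets in '", text,
                 "': expected <...> or {...}"))
  }
  body <- substr(text, 2, nchar(text) - 1)
  toks <- lapply(.tokenize_notation(body, text), .parse_token)

  is_bare_un <- vapply(toks, function(t) is.na(t$site), TRUE)
  if (any(is_bare_un) && length(toks) > 1) {
    abort("'un' (fully unmodified) must stand alone")
  }
  if (any(is_bare_un)) toks <- list()

  sites <- vapply(toks, `[[`, 0L, "site")
  if (anyDuplicated(sites)) {
    abort(paste0("duplicate site in '", text, "'"))
  }
  for (t in toks) {
    allowed <- .allowed_kinds(backbone, t$site)
    if (length(allowed) == 0) {
      abort(paste0("site ", t$site, " is not modifiable on ",
                   backbone$family))
    }
    real <- setdiff(t$kinds, "un")
    if (length(real) && !all(real %in% allowed)) {
      abort(paste0("kind(s) ", paste(setdiff(real, allowed), collapse = "/"),
                   " not allowed at site ", t$site, " on ", backbone$family))
    }
  }

  if (exact) {
    bad <- vapply(toks, function(t) length(t$kinds) > 1 || t$kinds[1] == "un",
                  TRUE)
    if (any(bad)) {
      abort("disjunctions and 'un' site constraints are query ({}) syntax")
    }
    ptms <- tibble(
      site = vapply(toks, `[[`, 0L, "site"),
      kind = vapply(toks, function(t) t$kinds[1], "")
    )
    return(proteoform(backbone, ptms))
  }
  if (length(toks) == 0) abort("a PTM query must be non-empty")
  ptm_query(
    backbone,
    tibble(
      site = vapply(toks, `[[`, 0L, "site"),
      kinds = lapply(toks, `[[`, "kinds")
    )
  )
}

#' Construct a PTM containment query
#'
#' @param backbone A [histone_backbone()].
#' @param constraints Tibble with integer `site` and list-column `kinds`;
#'   each element is a character vector of acceptable kinds at that site
#'   (`"un"` = site must be unmodified).
#' @return Object of class `ptm_query`.
#' @export
ptm_query <- function(backbone, constraints) {
  stopifnot(inherits(backbone, "histone_backbone"),
            nrow(constraints) >= 1)
  constraints <- constraints[order(constraints$site), ]
  structure(list(backbone = backbone, constraints = constraints),
            class = "ptm_query")
}

#' @export
print.ptm_query <- function(x, ...) {
  cat("<ptm_query> ", x$backbone$family, " ", format_notation(x), "\n",
      sep = "")
  invisible(x)
}

.format_site_token <- function(site, kinds) {
  if (site == 0L) return("N-ac")
  if (identical(kinds, "un")) return(paste0("K", site, "un"))
  if (length(kinds) == 1) return(paste0("K", site, kinds))
  degrees <- sub("^me", "", kinds)
  paste0("K", site, "me", paste(degrees, collapse = "/"))
}

#' Format a proteoform or query as canonical bracket notation
#'
#' Canonical ordering is N-terminus first, then ascending site. A fixed
#' N-terminal acetylation (H4) is implied and omitted; the fully unmodified
#' proteoform formats as `"<un>"`. `parse_notation(format_notation(x))`
#' round-trips to `x`.
#'
#' @param x A `proteoform` or `ptm_query`.
#' @return A single string.
#' @export
format_notation <- function(x) {
  if (inherits(x, "proteoform")) {
    ptms <- x$ptms
    if (x$backbone$n_term_ac_fixed) ptms <- ptms[ptms$site != 0L, ]
    if (nrow(ptms) == 0) return("<un>")
    toks <- vapply(seq_len(nrow(ptms)), function(i) {
      .format_site_token(ptms$site[i], ptms$kind[i])
    }, "")
    return(paste0("<", paste(toks, collapse = ""), ">"))
  }
  if (inherits(x, "ptm_query")) {
    cs <- x$constraints
    toks <- vapply(seq_len(nrow(cs)), function(i) {
      .format_site_token(cs$site[i], cs$kinds[[i]])
    }, "")
    return(paste0("{", paste(toks, collapse = ""), "}"))
  }
  abort("format_notation() expects a proteoform or ptm_query")
}

# Does an exact proteoform satisfy a containment query? Every constraint
# must hold: a "un" constraint means no PTM at the site; otherwise the
# proteoform's kind at the site must be one of the acceptable kinds.
#' Test whether a proteoform satisfies a containment query
#'
#' @param p A [proteoform()].
#' @param query A [ptm_query()] on the same backbone.
#' @return Logical scalar.
#' @export
satisfies_query <- function(p, query) {
  stopifnot(inherits(p, "proteoform"), inherits(query, "ptm_query"))
  cs <- query$constraints
  for (i in seq_len(nrow(cs))) {
    at <- p$ptms$kind[p$ptms$site == cs$site[i]]
    want <- cs$kinds[[i]]
    ok <- if (identical(want, "un")) length(at) == 0 else
      length(at) == 1 && at %in% want
    if (!ok) return(FALSE)
  }
  TRUE
}
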