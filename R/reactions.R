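# Reaction vocabulary and scheme construction.
#
# A CpG dyad is in one of three states: u (unmethylated), h (hemimethylated)
# or m (fully methylated). Methylation (+) and demethylation (-) reactions
# add or remove one methyl group: u->h, h->m, m->h, h->u. Collaborative
# reactions additionally require a mediator CpG in a specified state, e.g.
# "u+m" methylates a u target when an m mediator is drawn. The four
# self-destruction combinations (u-mediated methylation, m-mediated
# demethylation) are excluded from the catalogue.

SITE_STATES <- c("u", "h", "m")

REACTION_IDS <- c(
  "u+", "h+", "h-", "m-",
  "u+m", "u+h", "h+m", "h+h",
  "m-u", "m-h", "h-u", "h-h"
)

NONCOLLAB_IDS <- REACTION_IDS[1:4]
COLLAB_IDS <- REACTION_IDS[5:12]

MOTIF_NAMES <- c(
  "standard", "collaborative_full", "minimal", "full_feedback",
  "spatial_default"
)

#' The 12-reaction catalogue
#'
#' Returns the full catalogue of methylation/demethylation reactions: the
#' four non-collaborative reactions (`u+`, `h+`, `h-`, `m-`) and the eight
#' collaborative reactions in which a mediator CpG in state `m`, `h` or `u`
#' stimulates the transition at the target CpG. All reactions move a single
#' methyl group (u<->h<->m); the four self-destruction combinations
#' (u-mediated methylation, m-mediated demethylation) are not part of the
#' catalogue.
#'
#' @return A data frame with one row per reaction: `id`, `target` (required
#'   target state), `product` (state after completion), `direction` (`"+"`
#'   methylation, `"-"` demethylation), `mediator` (required mediator state,
#'   `NA` for non-collaborative reactions) and `collaborative`.
#' @examples
#' reaction_catalogue()
#' @export
reaction_catalogue <- function() {
  data.frame(
    id = REACTION_IDS,
    target = c("u", "h", "h", "m", "u", "u", "h", "h", "m", "m", "h", "h"),
    product = c("h", "m", "u", "h", "h", "h", "m", "m", "h", "h", "u", "u"),
    direction = c("+", "+", "-", "-", "+", "+", "+", "+",
                  "-", "-", "-", "-"),
    mediator = c(NA, NA, NA, NA, "m", "h", "m", "h", "u", "h", "u", "h"),
    collaborative = rep(c(FALSE, TRUE), c(4, 8)),
    stringsAsFactors = FALSE
  )
}

#' Does a reaction apply to a given target (and mediator)?
#'
#' A reaction completes if and only if the target CpG is in the reaction's
#' required target state and, for collaborative reactions, the mediator CpG
#' is in the required mediator state.
#'
#' @param id Reaction id (one of the 12 catalogue ids).
#' @param target Target site state (`"u"`, `"h"` or `"m"`).
#' @param mediator Mediator site state, or `NULL` for non-collaborative
#'   reactions. Supplying a mediator for a non-collaborative reaction (or
#'   omitting it for a collaborative one) is an error.
#' @return `TRUE` if the reaction would complete, `FALSE` otherwise.
#' @examples
#' reaction_applicability("u+m", "u", "m") # TRUE
#' reaction_applicability("u+", "h")       # FALSE: u+ cannot change an h
#' @export
reaction_applicability <- function(id, target, mediator = NULL) {
  cat <- reaction_catalogue()
  row <- cat[cat$id == id, ]
  if (nrow(row) != 1L) stop("unknown reaction id: ", id)
  target <- match.arg(target, SITE_STATES)
  if (row$collaborative) {
    if (is.null(mediator))
      stop("reaction ", id, " is collaborative and requires a mediator")
    mediator <- match.arg(mediator, SITE_STATES)
    target == row$target && mediator == row$mediator
  } else {
    if (!is.null(mediator))
      stop("reaction ", id, " is non-collaborative; no mediator applies")
    target == row$target
  }
}

#' Motif presets
#'
#' A motif is a named constraint set pinning a subset of the eight
#' collaborative reactions to rate zero (the four non-collaborative
#' reactions are never constrained; they act as noise floors). The presets
#' are:
#' \describe{
#'   \item{standard}{all eight collaborative rates pinned to 0; the
#'     classical site-independent maintenance model.}
#'   \item{collaborative_full}{no constraints; all 12 reactions free.}
#'   \item{minimal}{only the three collaborative methylation reactions
#'     `u+m`, `h+m`, `h+h` allowed, with non-collaborative demethylation
#'     carrying the U state.}
#'   \item{full_feedback}{the five favourable collaborative reactions
#'     `u+m`, `h+m`, `h+h`, `h-u`, `m-u`: positive feedback in both the
#'     methylation and demethylation directions.}
#'   \item{spatial_default}{the full-feedback constraint set with suggested
#'     rates tuned for the spatially restricted island-in-a-sea model.}
#' }
#' Suggested rates for the collaborative presets put collaborative
#' methylation near 0.2 and collaborative demethylation near 0.05, the
#' favoured regions found by scanning.
#'
#' @param name Preset name.
#' @return An object of class `motif_preset`: a list with `name`,
#'   `zero_constraints` (reaction ids pinned to 0) and `suggested_rates`.
#' @examples
#' motif_preset("full_feedback")$zero_constraints
#' @export
motif_preset <- function(name = MOTIF_NAMES) {
  name <- match.arg(name)
  zero <- switch(name,
    standard = COLLAB_IDS,
    collaborative_full = character(0),
    minimal = c("u+h", "m-u", "m-h", "h-u", "h-h"),
    full_feedback = c("u+h", "m-h", "h-h"),
    spatial_default = c("u+h", "m-h", "h-h")
  )
  suggested <- switch(name,
    standard = c("u+" = 1e-3, "h+" = 0.6, "h-" = 0.025, "m-" = 0.012),
    collaborative_full = NULL,
    minimal = c("u+" = 1e-4, "h+" = 1e-4, "h-" = 0.07, "m-" = 0.05,
                "u+m" = 0.2, "h+m" = 0.2, "h+h" = 0.2),
    full_feedback = c("u+" = 1e-4, "h+" = 1e-4, "h-" = 1e-3, "m-" = 1e-3,
                      "u+m" = 0.2, "h+m" = 0.2, "h+h" = 0.2,
                      "h-u" = 0.08, "m-u" = 0.08),
    spatial_default = c("u+" = 1e-4, "h+" = 1e-4, "h-" = 3e-4, "m-" = 1e-3,
                        "u+m" = 0.12, "h+m" = 0.12, "h+h" = 0.12,
                        "h-u" = 0.12, "m-u" = 0.30)
  )
  structure(list(name = name, zero_constraints = zero,
                 suggested_rates = suggested),
            class = "motif_preset")
}

resolve_motif <- function(motif) {
  if (inherits(motif, "motif_preset")) return(motif)
  if (is.character(motif) && length(motif) == 1L) return(motif_preset(motif))
  if (is.list(motif) && !is.null(motif$zero_constraints)) {
    if (is.null(motif$name)) motif$name <- "custom"
    return(structure(motif[c("name", "zero_constraints", "suggested_rates")],
                     class = "motif_preset"))
  }
  stop("motif must be a preset name, a motif_preset, or a list with ",
       "$zero_constraints")
}

#' Construct and validate a reaction scheme
#'
#' A reaction scheme assigns each of the 12 reactions a rate, interpreted
#' as an absolute per-attempt selection probability. The unassigned
#' remainder `1 - sum(rates)` is the probability that an attempt is a no-op,
#' so the rates must be non-negative and sum to at most 1. Rates of
#' reactions pinned to zero by the motif must be exactly 0.
#'
#' @param rates Named numeric vector or list of rates; reaction ids absent
#'   from `rates` default to 0. Unknown ids are an error.
#' @param motif Motif preset name or object constraining the scheme
#'   (default `"collaborative_full"`, i.e. unconstrained).
#' @return An object of class `reaction_scheme`: list with `rates` (named
#'   numeric, canonical catalogue order) and `motif`.
#' @examples
#' make_scheme(c("u+" = 1e-4, "h+" = 0.9, "h-" = 1e-3, "m-" = 1e-3),
#'             motif = "standard")
#' @export
make_scheme <- function(rates, motif = "collaborative_full") {
  motif <- resolve_motif(motif)
  rates <- unlist(rates)
  if (is.null(names(rates)) && length(rates) > 0)
    stop("rates must be named by reaction id")
  unknown <- setdiff(names(rates), REACTION_IDS)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  full <- stats::setNames(numeric(12), REACTION_IDS)
  full[names(rates)] <- as.numeric(rates)
  if (anyNA(full)) stop("rates must not contain NA")
  if (any(full < 0)) stop("rates must be non-negative")
  bad <- intersect(names(full)[full > 0], motif$zero_constraints)
  if (length(bad))
    stop("motif '", motif$name, "' pins reaction(s) ",
         paste(bad, collapse = ", "), " to zero")
  if (sum(full) > 1 + 1e-12)
    stop("rates sum to ", format(sum(full)),
         "; per-attempt selection probabilities must sum to at most 1")
  structure(list(rates = full, motif = motif$name),
            class = "reaction_scheme")
}

#' Scheme from a motif preset's suggested rates
#'
#' @param name Motif preset name with non-`NULL` suggested rates.
#' @return A validated `reaction_scheme`.
#' @examples
#' preset_scheme("full_feedback")
#' @export
preset_scheme <- function(name) {
  preset <- motif_preset(name)
  if (is.null(preset$suggested_rates))
    stop("motif '", name, "' has no suggested rates")
  make_scheme(preset$suggested_rates, motif = preset)
}

#' @export
print.reaction_scheme <- function(x, ...) {
  cat("Reaction scheme (motif: ", x$motif, ")\n", sep = "")
  nz <- x$rates[x$rates > 0]
  if (length(nz) == 0) {
    cat("  all rates zero\n")
  } else {
    for (id in names(nz))
      cat(sprintf("  %-4s %g\n", id, nz[[id]]))
  }
  cat("  no-op probability per attempt:", format(1 - sum(x$rates)), "\n")
  invisible(x)
}

#' Read / write a reaction scheme
#'
#' Schemes are stored as flat JSON maps from reaction id to rate plus a
#' `"motif"` key. Rates are written with 17 significant digits so that a
#' write/read round trip reproduces the rates map bit-exactly.
#'
#' @param scheme A `reaction_scheme`.
#' @param path File path.
#' @return `read_scheme` returns a `reaction_scheme`; `write_scheme`
#'   returns `path` invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "reaction_scheme"))
  obj <- c(as.list(scheme$rates), list(motif = scheme$motif))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  motif <- if (!is.null(obj$motif)) obj$motif else "collaborative_full"
  obj$motif <- NULL
  if (!motif %in% MOTIF_NAMES) {
    # scheme saved under an ad hoc motif (e.g. an ablation): keep the name,
    # drop constraints -- the rates themselves carry the zeros
    motif <- list(name = motif, zero_constraints = character(0))
  }
  make_scheme(unlist(obj), motif = motif)
}
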