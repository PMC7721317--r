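## Compartmented metabolic networks: containers, constructors, accessors.

COMPARTMENTS <- c(c = "cytosol", p = "plastid", m = "mitochondrion",
                  x = "peroxisome", v = "vacuole", e = "extracellular")

#' Construct a compartmented metabolic network
#'
#' The container used throughout the package: a metabolite table, a reaction
#' table with bounds and role tags, a sparse-triplet stoichiometry, and the
#' list of storable (metabolite, compartment) pairs eligible for diel linker
#' reactions.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (one of cytosol, plastid, mitochondrion, peroxisome, vacuole,
#'   extracellular), `carries_carbon`, `is_co2_species`, and optionally
#'   `carbons`, `nitrogens`.
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`, `tags`
#'   (list column of character vectors) and `boundary` (logical; exchange,
#'   sink and light-capture pseudo-reactions).
#' @param stoichiometry data.frame with columns `reaction`, `metabolite`,
#'   `coef` (signed; negative = consumed).
#' @param storables data.frame with columns `metabolite`, `compartment`.
#' @return object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry,
                              storables = NULL) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  stoichiometry <- as.data.frame(stoichiometry)
  stopifnot(all(c("id", "compartment") %in% names(metabolites)),
            all(c("id", "lb", "ub") %in% names(reactions)),
            all(c("reaction", "metabolite", "coef") %in% names(stoichiometry)))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (!all(metabolites$compartment %in% COMPARTMENTS))
    stop("unknown compartment(s): ",
         paste(setdiff(metabolites$compartment, COMPARTMENTS), collapse = ", "))
  bad <- setdiff(stoichiometry$metabolite, metabolites$id)
  if (length(bad))
    stop("stoichiometry references unknown metabolites: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(stoichiometry$reaction, reactions$id)
  if (length(bad))
    stop("stoichiometry references unknown reactions: ",
         paste(bad, collapse = ", "))
  if (any(reactions$lb > reactions$ub))
    stop("reaction(s) with lb > ub: ",
         paste(reactions$id[reactions$lb > reactions$ub], collapse = ", "))
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"carries_carbon" %in% names(metabolites))
    metabolites$carries_carbon <- FALSE
  if (!"is_co2_species" %in% names(metabolites))
    metabolites$is_co2_species <- FALSE
  if (any(metabolites$is_co2_species & !metabolites$carries_carbon))
    stop("is_co2_species implies carries_carbon")
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"tags" %in% names(reactions))
    reactions$tags <- replicate(nrow(reactions), character(0), simplify = FALSE)
  if (!"boundary" %in% names(reactions)) reactions$boundary <- FALSE
  structure(list(metabolites = metabolites, reactions = reactions,
                 stoichiometry = stoichiometry,
                 storables = storables %||% default_storables(metabolites)),
            class = "metabolic_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default storable pool: starch in the plastid; sugars, carboxylic acids,
#' proteinogenic amino acids and nitrate in the vacuole
#'
#' Only pairs whose metabolite actually exists in the network are kept.
#' @param metabolites metabolite table of a network.
#' @return data.frame with columns `metabolite`, `compartment`.
#' @export
default_storables <- function(metabolites) {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  want <- rbind(
    data.frame(base = "STARCH", compartment = "plastid"),
    data.frame(base = c("GLC", "FRU", "SUC", "MAL", "CIT", "ICIT", aa, "NO3"),
               compartment = "vacuole"))
  suffix <- c(plastid = "_p", vacuole = "_v")
  want$metabolite <- paste0(want$base, suffix[want$compartment])
  keep <- want$metabolite %in% metabolites$id
  out <- want[keep, c("metabolite", "compartment")]
  rownames(out) <- NULL
  out
}

#' Sparse stoichiometric matrix of a network
#'
#' @param net a [metabolic_network()].
#' @return a `dgCMatrix` with metabolites in rows, reactions in columns.
#' @export
stoich_matrix <- function(net) {
  mi <- match(net$stoichiometry$metabolite, net$metabolites$id)
  ri <- match(net$stoichiometry$reaction, net$reactions$id)
  Matrix::sparseMatrix(i = mi, j = ri, x = net$stoichiometry$coef,
                       dims = c(nrow(net$metabolites), nrow(net$reactions)),
                       dimnames = list(net$metabolites$id, net$reactions$id))
}

#' Find reactions carrying a role tag
#'
#' @param net a [metabolic_network()].
#' @param tag tag name, e.g. `"PEPC"`, `"ICDH_M"`, `"VACUOLAR_TRANSPORT"`.
#' @param several allow more than one match (vacuolar transporters).
#' @return character vector of reaction ids.
#' @export
find_tag <- function(net, tag, several = FALSE) {
  hit <- vapply(net$reactions$tags, function(tg) tag %in% tg, logical(1))
  ids <- net$reactions$id[hit]
  if (!length(ids))
    stop("configuration error: no reaction tagged '", tag, "'")
  if (!several && length(ids) > 1)
    stop("tag '", tag, "' matches several reactions: ",
         paste(ids, collapse = ", "))
  ids
}

## Roles the diel assembly needs to resolve.
REQUIRED_TAGS <- c("PHLOEM_EXPORT", "NITRATE_UPTAKE", "CO2_UPTAKE",
                   "RUBISCO_CARB", "RUBISCO_OXY", "ATP_MAINT",
                   "NADPH_MAINT", "LIGHT_UPTAKE")

#' Check that all roles required by the diel assembly resolve to reactions
#'
#' @param net a [metabolic_network()].
#' @return invisibly, a named character vector of resolved reaction ids.
#' @export
check_required_tags <- function(net) {
  res <- vapply(REQUIRED_TAGS, function(tg) find_tag(net, tg), character(1))
  invisible(res)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions (", sum(x$reactions$boundary),
      " boundary), ", nrow(x$storables), " storables\n", sep = "")
  tab <- table(x$metabolites$compartment)
  cat("  compartments:",
      paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

## Parse "2 A_c + B_c -> C_p" / "<->" equation strings into triplets.
parse_rxn_eq <- function(id, eq) {
  arrow <- if (grepl("<->", eq, fixed = TRUE)) "<->" else "->"
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(NULL)
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- lapply(terms, function(tm) {
      parts <- strsplit(tm, "\\s+")[[1]]
      if (length(parts) == 2)
        data.frame(reaction = id, metabolite = parts[2],
                   coef = sign * as.numeric(parts[1]))
      else data.frame(reaction = id, metabolite = parts[1], coef = sign * 1)
    })
    do.call(rbind, out)
  }
  rbind(parse_side(sides[1], -1), parse_side(sides[2], 1))
}

#' Stoichiometric consistency of the internal network
#'
#' Searches, by linear programming, for a strictly positive metabolite
#' weighting `w >= 1` with `t(S_int) %*% w = 0` over the internal (non
#' extracellular-facing, non-boundary) part of the network, i.e. a
#' generalized mass assignment under which no internal reaction creates or
#' destroys matter.
#'
#' @param net a [metabolic_network()].
#' @return list with `consistent` (logical) and, when consistent, the
#'   weighting `w` (named, internal metabolites only).
#' @export
stoichiometric_consistency <- function(net) {
  S <- stoich_matrix(net)
  ext <- net$metabolites$id[net$metabolites$compartment == "extracellular"]
  touches_ext <- colnames(S) %in%
    unique(net$stoichiometry$reaction[net$stoichiometry$metabolite %in% ext])
  internal_rxn <- !net$reactions$boundary & !touches_ext
  used <- Matrix::rowSums(abs(S[, internal_rxn, drop = FALSE])) > 0
  Si <- S[used, internal_rxn, drop = FALSE]
  nm <- nrow(Si)
  if (!nm) return(list(consistent = TRUE, w = numeric(0)))
  ## feasibility LP: min sum(w), t(Si) w = 0, 1 <= w <= big
  r <- solve_program(rep(1, nm), Matrix::t(Si), numeric(ncol(Si)),
                     sense = rep("=", ncol(Si)),
                     lb = rep(1, nm), ub = rep(1e6, nm))
  if (r$status != "optimal") return(list(consistent = FALSE, w = NULL))
  w <- r$x
  names(w) <- rownames(Si)
  list(consistent = TRUE, w = w)
}
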