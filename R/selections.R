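#' Atom selection mini-language
#'
#' Selections are resolved against a trajectory's atom table with a small,
#' fully specified grammar (whitespace-tokenized, case-sensitive values):
#'
#' \preformatted{
#'   expr    := or_expr
#'   or_expr := and_expr ("or" and_expr)*
#'   and_expr:= unary ("and" unary)*
#'   unary   := "not" unary | "(" expr ")" | term
#'   term    := "protein" | "all" | "hydrogen" | "heavy"
#'            | "name"    value+
#'            | "resname" value+
#'            | "segid"   value+
#'            | "resid"   int+        (single integers, no ranges)
#' }
#'
#' A field term matches atoms whose field equals any of the listed values
#' (exact string match; \code{resid} compares integers). \code{protein}
#' matches the 20 standard amino-acid residue names plus common histidine
#' variants (HSD/HSE/HSP). \code{hydrogen}/\code{heavy} test the
#' \code{is_hydrogen} flag set at load time. \code{and} binds tighter than
#' \code{or}; \code{not} tighter than both.
#'
#' @param atoms atom table (data.frame with columns \code{name},
#'   \code{resname}, \code{resid}, \code{segid}, \code{is_hydrogen}), as
#'   stored in a \code{trajectory}.
#' @param expr selection expression string.
#' @return integer vector of atom row indices (possibly empty).
#' @examples
#' atoms <- data.frame(name = c("CA", "P1"), resname = c("GLY", "PG"),
#'                     resid = c(1L, 100L), segid = c("PROA", "MEMB"),
#'                     is_hydrogen = FALSE)
#' select_atoms(atoms, "protein")
#' select_atoms(atoms, "segid MEMB and name P1 P2")
#' @export
select_atoms <- function(atoms, expr) {
  which(selection_mask(atoms, expr))
}

.protein_resnames <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP"
)

.sel_keywords <- c("and", "or", "not", "(", ")",
                   "name", "resname", "segid", "resid",
                   "protein", "all", "hydrogen", "heavy")

selection_mask <- function(atoms, expr) {
  if (!is.character(expr) || length(expr) != 1L || !nzchar(trimws(expr))) {
    stop("selection expression must be a non-empty string")
  }
  spaced <- gsub("([()])", " \\1 ", expr)
  tokens <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  mask <- .sel_or(state, atoms)
  if (state$pos <= length(state$tokens)) {
    stop("trailing tokens in selection '", expr, "' at '",
         state$tokens[state$pos], "'")
  }
  mask
}

.sel_peek <- function(state) {
  if (state$pos > length(state$tokens)) NA_character_ else state$tokens[state$pos]
}
.sel_next <- function(state) {
  tok <- .sel_peek(state)
  if (is.na(tok)) stop("unexpected end of selection expression")
  state$pos <- state$pos + 1L
  tok
}

.sel_or <- function(state, atoms) {
  mask <- .sel_and(state, atoms)
  while (identical(.sel_peek(state), "or")) {
    .sel_next(state)
    mask <- mask | .sel_and(state, atoms)
  }
  mask
}

.sel_and <- function(state, atoms) {
  mask <- .sel_unary(state, atoms)
  while (identical(.sel_peek(state), "and")) {
    .sel_next(state)
    mask <- mask & .sel_unary(state, atoms)
  }
  mask
}

.sel_unary <- function(state, atoms) {
  tok <- .sel_peek(state)
  if (is.na(tok)) stop("unexpected end of selection expression")
  if (tok == "not") {
    .sel_next(state)
    return(!.sel_unary(state, atoms))
  }
  if (tok == "(") {
    .sel_next(state)
    mask <- .sel_or(state, atoms)
    if (!identical(.sel_peek(state), ")")) stop("unbalanced '(' in selection")
    .sel_next(state)
    return(mask)
  }
  .sel_term(state, atoms)
}

.sel_values <- function(state) {
  vals <- character()
  repeat {
    tok <- .sel_peek(state)
    if (is.na(tok) || tok %in% .sel_keywords) break
    vals <- c(vals, .sel_next(state))
  }
  if (!length(vals)) stop("field selector requires at least one value")
  vals
}

.sel_term <- function(state, atoms) {
  tok <- .sel_next(state)
  switch(tok,
    protein = atoms$resname %in% .protein_resnames,
    all = rep(TRUE, nrow(atoms)),
    hydrogen = atoms$is_hydrogen,
    heavy = !atoms$is_hydrogen,
    name = atoms$name %in% .sel_values(state),
    resname = atoms$resname %in% .sel_values(state),
    segid = atoms$segid %in% .sel_values(state),
    resid = {
      vals <- suppressWarnings(as.integer(.sel_values(state)))
      if (anyNA(vals)) stop("'resid' values must be integers")
      atoms$resid %in% vals
    },
    stop("unknown selection token '", tok, "'")
  )
}

#' Selection specification for a membrane-protein system
#'
#' Bundles the named selections every analysis module needs: the protein,
#' the heme (porphyrin) ring, lipid head-group phosphorus and nitrogen
#' atoms, the lipid carbonyl particles, a residue-name to lipid-type map,
#' and which leaflet the protein binds.
#'
#' @param protein selection for all protein atoms.
#' @param heme_ring selection for the porphyrin ring heavy atoms (>= 3,
#'   non-collinear) used for plane fitting.
#' @param headgroup_P selection for head-group phosphorus atoms.
#' @param headgroup_N selection for head-group nitrogen atoms; may resolve
#'   to zero atoms (PG and CDL carry no head-group nitrogen).
#' @param carbonyl selection for lipid carbonyl atoms defining the
#'   hydrophobic-insertion plane; may be \code{NULL} if insertion analysis
#'   is not used.
#' @param lipid_type_map named character vector mapping lipid residue names
#'   to types \code{CDL}, \code{PE}, \code{PG}, \code{PC}; unmapped residue
#'   names are typed \code{OTHER}.
#' @param binding_leaflet \code{"upper"} or \code{"lower"}.
#' @return object of class \code{selection_spec}.
#' @seealso [select_atoms()] for the expression grammar,
#'   [synthetic_selections()] for the spec matching generated systems.
#' @export
selection_spec <- function(protein, heme_ring = NULL,
                           headgroup_P, headgroup_N = NULL,
                           carbonyl = NULL,
                           lipid_type_map = c(CDL = "CDL", PE = "PE",
                                              PG = "PG", PC = "PC"),
                           binding_leaflet = c("upper", "lower")) {
  binding_leaflet <- match.arg(binding_leaflet)
  if (is.null(names(lipid_type_map)) || any(!nzchar(names(lipid_type_map)))) {
    stop("lipid_type_map must be a named character vector (resname -> type)")
  }
  bad <- setdiff(unique(lipid_type_map), c("CDL", "PE", "PG", "PC", "OTHER"))
  if (length(bad)) stop("unknown lipid types in lipid_type_map: ",
                        paste(bad, collapse = ", "))
  structure(list(protein = protein, heme_ring = heme_ring,
                 headgroup_P = headgroup_P, headgroup_N = headgroup_N,
                 carbonyl = carbonyl, lipid_type_map = lipid_type_map,
                 binding_leaflet = binding_leaflet),
            class = "selection_spec")
}

# Resolve every selection in a spec against an atom table; errors if a
# mandatory selection is empty (headgroup_N and absent optional entries may
# be empty). Returns a list of integer index vectors.
resolve_selections <- function(atoms, spec) {
  stopifnot(inherits(spec, "selection_spec"))
  fields <- c("protein", "heme_ring", "headgroup_P", "headgroup_N", "carbonyl")
  out <- list()
  for (f in fields) {
    if (is.null(spec[[f]])) { out[[f]] <- integer(); next }
    idx <- select_atoms(atoms, spec[[f]])
    if (!length(idx) && f != "headgroup_N") {
      stop("selection '", f, "' (", spec[[f]], ") matches no atoms")
    }
    out[[f]] <- idx
  }
  out$lipid_type_map <- spec$lipid_type_map
  out$binding_leaflet <- spec$binding_leaflet
  out
}

# Lipid type of a residue-name vector under a spec's map.
lipid_type_of <- function(resname, lipid_type_map) {
  typ <- unname(lipid_type_map[resname])
  typ[is.na(typ)] <- "OTHER"
  typ
}
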