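#' Catalytic site models and active-site integrity calling
#'
#' PPM-family (PP2C-type) Ser/Thr phosphatases require at least two divalent
#' metal ions, M1 and M2, coordinated by a conserved constellation of acidic
#' residues, for catalysis; a third site, M3, is dispensable. A
#' `catalytic_site_model` lists those coordinating positions in the numbering
#' of a reference sequence (typically PPM1A), the residues allowed at each,
#' and whether the position is required for activity. Sequences whose aligned
#' residues violate a required M1 or M2 position are called pseudo
#' (pseudophosphatase-like).
#'
#' @name active_site
NULL

#' Build a catalytic site model
#'
#' @param reference_id Label of the reference sequence in alignments.
#' @param role Character vector in `{"M1","M2","M3"}`.
#' @param position 1-based residue positions in the ungapped reference,
#'   strictly increasing.
#' @param allowed Character vector; each element the residues allowed at that
#'   position, as a string of one-letter codes (e.g. `"DE"`).
#' @param required Logical vector; required positions enter the activity rule.
#' @return A data frame of class `catalytic_site_model`.
#' @export
site_model <- function(reference_id, role, position, allowed, required) {
  stopifnot(length(role) == length(position), length(allowed) == length(position),
            length(required) == length(position))
  if (length(position) == 0L) stop_invalid("site model must have at least one position")
  if (!all(role %in% c("M1", "M2", "M3"))) stop_invalid("roles must be M1, M2 or M3")
  if (any(diff(position) <= 0)) stop_invalid("positions must be strictly increasing")
  if (any(nchar(allowed) == 0)) stop_invalid("allowed residue sets must be nonempty")
  required <- as.logical(required)
  if (!any(required & role == "M1") || !any(required & role == "M2")) {
    stop_invalid("model needs at least one required M1 and one required M2 position (the activity rule needs both metals)")
  }
  m <- data.frame(role = role, position = as.integer(position),
                  allowed = toupper(allowed), required = required,
                  stringsAsFactors = FALSE)
  attr(m, "reference_id") <- reference_id
  class(m) <- c("catalytic_site_model", "data.frame")
  m
}

#' Default PPM1A metal-coordination site model
#'
#' The binuclear-site model shipped with the package, in PPM1A residue
#' numbering, transcribed from the standard structural literature on the
#' PPM1A active site: E37/D38/D60 coordinating M1, D60/D239/D282 coordinating
#' M2 (D60 bridges both metals and is listed once, under M1), and D146 at the
#' dispensable M3 site. Aspartate positions allow only D by default; the
#' conservative mode additionally allows the other acidic residue (E at D
#' positions, D at E positions). M3 is reported but never enters the activity
#' rule. The numbering is configurable: load an alternative model with
#' [read_site_model()] rather than editing code.
#'
#' @param reference_id Label the reference sequence carries in alignments.
#' @param conservative If `TRUE`, acidic positions allow both D and E.
#' @return A `catalytic_site_model`.
#' @export
default_site_model <- function(reference_id = "PPM1A", conservative = FALSE) {
  asp <- if (conservative) "DE" else "D"
  glu <- if (conservative) "ED" else "E"
  site_model(
    reference_id = reference_id,
    role     = c("M1", "M1", "M1", "M3", "M2", "M2"),
    position = c(37L, 38L, 60L, 146L, 239L, 282L),
    allowed  = c(glu, asp, asp, asp, asp, asp),
    required = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
}

#' Read a catalytic site model from JSON or TSV
#'
#' JSON files carry `reference_id` and a `sites` array of
#' `{role, position, allowed, required}` records; TSV files carry columns
#' `role`, `position`, `allowed`, `required` (the reference id is then given
#' via `reference_id`).
#'
#' @param path File path (`.json` or tab-separated text).
#' @param reference_id Reference label, required for TSV input.
#' @return A `catalytic_site_model`.
#' @export
read_site_model <- function(path, reference_id = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    s <- as.data.frame(j$sites)
    return(site_model(j$reference_id %||% reference_id, s$role, s$position,
                      s$allowed, s$required))
  }
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(reference_id)) stop_invalid("reference_id is required for TSV site models")
  site_model(reference_id, s$role, s$position, s$allowed, as.logical(s$required))
}

# Coerce an alignment (named character vector, list, or Biostrings
# AAStringSet) to a named character vector of equal-length rows.
as_alignment <- function(alignment) {
  if (inherits(alignment, "AAStringSet") || inherits(alignment, "XStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  alignment <- unlist(alignment)
  if (length(alignment) == 0L) stop_invalid("alignment is empty")
  if (is.null(names(alignment)) || any(names(alignment) == "")) {
    stop_invalid("alignment sequences must be named")
  }
  if (length(unique(nchar(alignment))) != 1L) {
    stop_invalid("aligned sequences must all have the same length")
  }
  toupper(alignment)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned amino-acid FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  as_alignment(Biostrings::readAAStringSet(path))
}

#' Write an alignment to FASTA
#'
#' @param alignment Named character vector of aligned sequences.
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(as_alignment(alignment)), path)
  invisible(path)
}

#' Map reference residue positions to alignment columns
#'
#' For each model position k, returns the alignment column holding the k-th
#' non-gap character of the reference row.
#'
#' @param alignment Alignment (see [read_alignment()]).
#' @param model A `catalytic_site_model`.
#' @return Named integer vector: reference position -> 1-based column.
#' @export
map_reference_positions <- function(alignment, model) {
  alignment <- as_alignment(alignment)
  ref_id <- attr(model, "reference_id")
  if (!ref_id %in% names(alignment)) {
    stop_invalid("reference sequence '%s' not found in alignment", ref_id)
  }
  ref <- strsplit(alignment[[ref_id]], "")[[1]]
  nongap <- ref != "-" & ref != "."
  cols <- which(nongap)
  if (max(model$position) > length(cols)) {
    stop_invalid("model position %d beyond ungapped reference length %d",
                 max(model$position), length(cols))
  }
  stats::setNames(cols[model$position], model$position)
}

#' Call active-site integrity per sequence
#'
#' Classifies each sequence of an alignment as catalytically `active` or
#' `pseudo` from the residues it carries at the model's metal-coordination
#' positions: `active` iff every required M1 and M2 position holds an allowed
#' residue. A gap at a required position counts as a mismatch (a deleted
#' coordinating residue cannot bind metal). M3 positions are reported but do
#' not affect the class. `m2_zinc_flag` marks sequences with a cysteine at any
#' M2-role column -- the signature of an M2 site converted into a structural
#' zinc-binding site, as in the C799/D820/D822/D1024 constellation of human
#' PHLPP2.
#'
#' @param alignment Alignment (named character vector or `AAStringSet`).
#' @param model A `catalytic_site_model`.
#' @return A data frame of class `active_site_calls`: one row per sequence
#'   with `sequence_id`, `class` (`active`/`pseudo`/`ambiguous`),
#'   `m2_zinc_flag`, `n_required`, `n_required_matched`. The per-site detail
#'   (role, position, column, residue, matched) is in `attr(, "sites")`.
#' @export
call_active_site <- function(alignment, model) {
  alignment <- as_alignment(alignment)
  colmap <- map_reference_positions(alignment, model)
  cols <- unname(colmap)
  chars <- strsplit(alignment, "")
  allowed_sets <- strsplit(model$allowed, "")
  req_idx <- which(model$required & model$role %in% c("M1", "M2"))
  m2_idx <- which(model$role == "M2")

  detail <- vector("list", length(alignment))
  calls <- data.frame(
    sequence_id = names(alignment),
    class = NA_character_,
    m2_zinc_flag = NA,
    n_required = length(req_idx),
    n_required_matched = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(alignment)) {
    res <- chars[[i]][cols]
    matched <- mapply(function(r, a) r %in% a, res, allowed_sets)
    calls$n_required_matched[i] <- sum(matched[req_idx])
    calls$class[i] <- if (all(matched[req_idx])) "active" else "pseudo"
    calls$m2_zinc_flag[i] <- any(res[m2_idx] == "C")
    detail[[i]] <- data.frame(
      sequence_id = names(alignment)[i], role = model$role,
      position = model$position, column = cols, residue = res,
      matched = unname(matched), required = model$required,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  attr(calls, "sites") <- do.call(rbind, detail)
  class(calls) <- c("active_site_calls", "data.frame")
  calls
}

#' Residue conservation profile of alignment columns
#'
#' Per-column residue frequencies over non-gap characters and the information
#' content in bits, `log2(20) - H`, where H is the Shannon entropy of the
#' column's residue distribution -- the quantity plotted by sequence logos.
#'
#' @param alignment Alignment.
#' @param columns Integer vector of 1-based alignment columns.
#' @return List with `freq` (20 x length(columns) matrix of frequencies,
#'   rows named by residue) and `ic` (named numeric, bits; `NA` for all-gap
#'   columns, which are undefined rather than an error).
#' @export
conservation_profile <- function(alignment, columns) {
  alignment <- as_alignment(alignment)
  width <- nchar(alignment[[1]])
  columns <- as.integer(columns)
  if (any(columns < 1L | columns > width)) {
    stop_invalid("columns must lie in [1, %d]", width)
  }
  chars <- do.call(rbind, strsplit(alignment, ""))
  freq <- matrix(NA_real_, nrow = length(AA_ALPHABET20), ncol = length(columns),
                 dimnames = list(AA_ALPHABET20, as.character(columns)))
  ic <- stats::setNames(rep(NA_real_, length(columns)), as.character(columns))
  for (j in seq_along(columns)) {
    col <- chars[, columns[j]]
    col <- col[col %in% AA_ALPHABET20]
    if (length(col) == 0L) next  # all-gap column: undefined, not an error
    f <- table(factor(col, levels = AA_ALPHABET20)) / length(col)
    freq[, j] <- as.numeric(f)
    p <- f[f > 0]
    ic[j] <- log2(20) - sum(-p * log2(p))
  }
  list(freq = freq, ic = ic)
}

#' Convert active-site calls to a binary tip character
#'
#' Encodes calls as a presence/absence character of the intact active site
#' (`active` -> 1, `pseudo` -> 0, `ambiguous` -> `NA`) suitable for
#' [infer_dollo()], so active-site loss can be mapped on a phylogeny.
#'
#' @param calls An `active_site_calls` data frame.
#' @param drop Sequence ids to exclude (e.g. the model's reference sequence,
#'   which is usually not a tree tip).
#' @return Named integer vector of states.
#' @export
activity_character <- function(calls, drop = character(0)) {
  stopifnot(inherits(calls, "active_site_calls") || is.data.frame(calls))
  calls <- calls[!calls$sequence_id %in% drop, , drop = FALSE]
  stats::setNames(
    ifelse(calls$class == "active", 1L, ifelse(calls$class == "pseudo", 0L, NA_integer_)),
    calls$sequence_id
  )
}
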