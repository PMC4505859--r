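#' Coarse-grained bead topology
#'
#' A `bead_topology` is a data frame with one row per coarse-grained bead,
#' describing its identity and role independently of any coordinates. It is
#' the static half of a system; the dynamic half is a [frame()].
#'
#' Columns:
#' \describe{
#'   \item{bead_id}{integer, unique and contiguous from 0; row order follows
#'     bead_id, so row `i` holds bead `i - 1`.}
#'   \item{bead_name}{short bead label (e.g. `"BB"`, `"NC3"`, `"P1"`).}
#'   \item{residue_id}{integer residue number (protein residues; lipids use
#'     one residue per molecule).}
#'   \item{residue_name}{residue label (`"LYS"`, `"DOPC"`, `"PIP2"`, ...).}
#'   \item{molecule_id}{integer molecule index, contiguous from 1.}
#'   \item{molecule_class}{one of `"protein"`, `"DOPC"`, `"PIP2"`, `"ion"`.}
#'   \item{charge}{bead charge in elementary-charge units.}
#'   \item{is_phosphate}{logical; `TRUE` only for PIP2 head phosphate beads,
#'     which are the reference beads of the binding criterion.}
#'   \item{leaflet}{`"upper"` or `"lower"` for lipid beads, `NA` otherwise.}
#' }
#'
#' @param df data frame holding the columns above.
#' @return `df` with class `bead_topology`, validated.
#' @export
bead_topology <- function(df) {
  required <- c("bead_id", "bead_name", "residue_id", "residue_name",
                "molecule_id", "molecule_class", "charge", "is_phosphate",
                "leaflet")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("bead_topology is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df <- df[order(df$bead_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("bead_topology", "data.frame")
  validate_topology(df)
  df
}

#' Validate a bead topology's structural invariants
#'
#' Checks id contiguity, molecule-class vocabulary, the PIP2/phosphate
#' correspondence, and leaflet flags (defined for lipids, undefined
#' otherwise). Called by [bead_topology()]; exported so readers can re-check
#' after file ingestion.
#'
#' @param top a `bead_topology`.
#' @return `top`, invisibly; stops on violation.
#' @export
validate_topology <- function(top) {
  n <- nrow(top)
  if (n == 0) stop("topology has no beads", call. = FALSE)
  if (!identical(as.integer(top$bead_id), 0:(n - 1L))) {
    stop("bead_ids must be unique and contiguous from 0", call. = FALSE)
  }
  bad_class <- setdiff(unique(top$molecule_class),
                       c("protein", "DOPC", "PIP2", "ion"))
  if (length(bad_class) > 0) {
    stop("unknown molecule_class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  if (any(top$is_phosphate & top$molecule_class != "PIP2")) {
    stop("is_phosphate beads must belong to PIP2 molecules", call. = FALSE)
  }
  pip_mols <- unique(top$molecule_id[top$molecule_class == "PIP2"])
  phos_mols <- unique(top$molecule_id[top$is_phosphate])
  if (length(setdiff(pip_mols, phos_mols)) > 0) {
    stop("every PIP2 molecule needs at least one phosphate bead", call. = FALSE)
  }
  is_lipid <- top$molecule_class %in% c("DOPC", "PIP2")
  if (any(is_lipid & !top$leaflet %in% c("upper", "lower"))) {
    stop("lipid beads must carry a leaflet flag ('upper'/'lower')", call. = FALSE)
  }
  if (any(!is_lipid & !is.na(top$leaflet))) {
    stop("leaflet flag must be NA for non-lipid beads", call. = FALSE)
  }
  if (!all(is.finite(top$charge))) stop("charges must be finite", call. = FALSE)
  invisible(top)
}

#' Single trajectory frame
#'
#' Coordinates (nm) plus an orthorhombic box and a time stamp.
#'
#' @param coords numeric matrix, one row per bead, columns x/y/z in nm.
#' @param box numeric length-3 vector of box edge lengths in nm.
#' @param time time stamp in ns.
#' @return object of class `cg_frame`.
#' @export
frame <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have 3 columns", call. = FALSE)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) {
    stop("box must be three positive edge lengths", call. = FALSE)
  }
  dimnames(coords) <- NULL
  structure(list(coords = coords, box = box, time = as.numeric(time)),
            class = "cg_frame")
}

#' Trajectory: a topology plus time-ordered frames
#'
#' @param topology a [bead_topology()].
#' @param frames list of [frame()] objects with strictly increasing times and
#'   bead counts matching the topology.
#' @return object of class `cg_trajectory`.
#' @export
trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "bead_topology"))
  if (length(frames) == 0) stop("trajectory needs at least one frame", call. = FALSE)
  nb <- nrow(topology)
  for (fr in frames) {
    if (!inherits(fr, "cg_frame")) stop("frames must be cg_frame objects", call. = FALSE)
    if (nrow(fr$coords) != nb) {
      stop("frame bead count (", nrow(fr$coords), ") != topology bead count (",
           nb, ")", call. = FALSE)
    }
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(topology = topology, frames = frames), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  times <- vapply(x$frames, function(f) f$time, numeric(1))
  cat(sprintf("cg_trajectory: %d beads, %d frames, t = %g..%g ns\n",
              nrow(x$topology), length(x$frames), min(times), max(times)))
  tab <- table(x$topology$molecule_class)
  cat("  beads by class:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.bead_topology <- function(x, ...) {
  tab <- table(x$molecule_class)
  cat(sprintf("bead_topology: %d beads (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
  NextMethod()
}

# --- selectors (bead ids are 0-based; row index = bead_id + 1) ---------------

#' Bead-id selectors
#'
#' Convenience selectors returning 0-based bead ids for the groups the
#' analyses keep referring to.
#'
#' @param top a `bead_topology`.
#' @return integer vector of bead ids.
#' @name selectors
NULL

#' @rdname selectors
#' @export
protein_beads <- function(top) top$bead_id[top$molecule_class == "protein"]

#' @rdname selectors
#' @export
phosphate_beads <- function(top) top$bead_id[top$is_phosphate]

#' @rdname selectors
#' @param leaflet `"upper"` or `"lower"`.
#' @export
leaflet_beads <- function(top, leaflet) {
  top$bead_id[!is.na(top$leaflet) & top$leaflet == leaflet]
}

#' @rdname selectors
#' @param class molecule class name.
#' @export
class_beads <- function(top, class) top$bead_id[top$molecule_class == class]

#' Count molecules of a class
#' @param top a `bead_topology`.
#' @param class molecule class name.
#' @return integer count of distinct molecules.
#' @export
n_molecules <- function(top, class) {
  length(unique(top$molecule_id[top$molecule_class == class]))
}
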