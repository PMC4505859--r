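# Readers/writers for on-disk artifacts: fixed-column GRO coordinates
# (single- and multi-frame), tabular topology sidecars, PDB structures (via
# bio3d), result tables with a reproducibility header, and the packaged
# residue-contact fixture.

TABLE3_MD5 <- "144d689f6a8f773247f3bfc5c5e96843"
SITES_MD5 <- "adacf9532aad569b6df2d706485fb621"

#' Write coordinates as (multi-frame) GRO
#'
#' Fixed-column GROMACS GRO dialect, nm units, 3 decimals. Multiple frames
#' are concatenated, each with a `t=` stamp in its title line. Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param path output file.
#' @param topology a [bead_topology()].
#' @param frames a single [frame()] or a list of frames.
#' @param title title prefix for each frame block.
#' @return `path`, invisibly.
#' @export
write_gro <- function(path, topology, frames, title = "pipbind system") {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- nrow(topology)
  resid <- topology$residue_id %% 100000L
  atomid <- (topology$bead_id + 1L) %% 100000L
  for (fr in frames) {
    if (nrow(fr$coords) != n) {
      stop("frame bead count does not match topology", call. = FALSE)
    }
    writeLines(sprintf("%s t= %.5f", title, fr$time), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid, substr(topology$residue_name, 1, 5),
                       substr(topology$bead_name, 1, 5), atomid,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]),
               con)
  }
  invisible(path)
}

#' Read a (multi-frame) GRO file
#'
#' Parses the fixed-column GRO dialect. Returns the per-atom metadata the
#' format carries (a partial topology: residue ids/names and bead names) and
#' all frames found. Malformed count lines or truncated frames raise a parse
#' error naming the offending line.
#'
#' @param path GRO file.
#' @return list with `atoms` (data frame: residue_id, residue_name,
#'   bead_name), `frame` (first frame) and `frames` (list of all frames).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) stop("GRO parse error: empty file", call. = FALSE)
  frames <- list()
  atoms <- NULL
  pos <- 1L
  while (pos <= length(lines)) {
    if (pos + 1L > length(lines)) {
      stop("GRO parse error at line ", pos, ": truncated frame header",
           call. = FALSE)
    }
    title <- lines[pos]
    n <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(n) || n < 1) {
      stop("GRO parse error at line ", pos + 1L, ": malformed atom count line",
           call. = FALSE)
    }
    if (pos + 1L + n + 1L > length(lines)) {
      stop("GRO parse error at line ", length(lines),
           ": truncated frame (expected ", n, " atoms)", call. = FALSE)
    }
    al <- lines[(pos + 2L):(pos + 1L + n)]
    xyz <- cbind(suppressWarnings(as.numeric(substr(al, 21, 28))),
                 suppressWarnings(as.numeric(substr(al, 29, 36))),
                 suppressWarnings(as.numeric(substr(al, 37, 44))))
    if (any(!is.finite(xyz))) {
      bad <- pos + 1L + which(!is.finite(rowSums(xyz)))[1]
      stop("GRO parse error at line ", bad, ": unreadable coordinates",
           call. = FALSE)
    }
    boxline <- lines[pos + 1L + n + 1L]
    box <- suppressWarnings(as.numeric(strsplit(trimws(boxline), "\\s+")[[1]]))
    if (length(box) < 3 || any(!is.finite(box[1:3]))) {
      stop("GRO parse error at line ", pos + 1L + n + 1L,
           ": malformed box line", call. = FALSE)
    }
    time <- 0
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(tm) == 1) time <- as.numeric(sub("t=\\s*", "", tm))
    if (is.null(atoms)) {
      atoms <- data.frame(
        residue_id = as.integer(substr(al, 1, 5)),
        residue_name = trimws(substr(al, 6, 10)),
        bead_name = trimws(substr(al, 11, 15)),
        stringsAsFactors = FALSE
      )
    }
    frames[[length(frames) + 1L]] <- frame(xyz, box[1:3], time)
    pos <- pos + n + 3L
  }
  list(atoms = atoms, frame = frames[[1]], frames = frames)
}

#' Write / read the bead-topology sidecar (TSV)
#'
#' Lossless round trip of every [bead_topology()] field; unknown extra
#' columns survive the trip. The reader names any missing required column in
#' its error and rejects non-ASCII minus signs in numeric columns rather
#' than silently coercing them.
#'
#' @param topology a [bead_topology()].
#' @param path TSV file.
#' @return `write_topology_tsv`: `path` invisibly; `read_topology_tsv`: a
#'   [bead_topology()].
#' @export
write_topology_tsv <- function(topology, path) {
  utils::write.table(as.data.frame(topology), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_topology_tsv
#' @export
read_topology_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, encoding = "UTF-8")
  if (any(grepl("−", raw))) {
    stop("topology schema error: non-ASCII minus sign (U+2212) in numeric ",
         "field; use the ASCII '-'", call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("bead_id", "bead_name", "residue_id", "residue_name",
                "molecule_id", "molecule_class", "charge", "is_phosphate",
                "leaflet")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("topology schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$is_phosphate <- as.logical(df$is_phosphate)
  df$leaflet <- as.character(df$leaflet)
  df$leaflet[df$leaflet %in% c("", "NA")] <- NA_character_
  bead_topology(df)
}

#' Write an elastic network as TSV
#' @param net [build_elastic_network()] output.
#' @param path TSV file.
#' @export
write_elastic_tsv <- function(net, path) {
  utils::write.table(as.data.frame(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a result table with a reproducibility header
#'
#' Emits `# key: value` comment lines (tool version, seed, config hash, and
#' any extra metadata) followed by a TSV body. Use [read_result_tsv()] to
#' read it back.
#'
#' @param df data frame.
#' @param path output TSV.
#' @param meta named list of metadata values.
#' @export
write_result_tsv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# pipbind_version: %s",
                     as.character(utils::packageVersion("pipbind"))), con)
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, as.character(meta[[nm]])), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Load the packaged residue-contact matrix fixture
#'
#' Per-residue contact percentages for three independent membrane-association
#' simulations over the 15 basic residues of the FAK FERM/kinase surface
#' (K191..R665), shipped as a plain-text table. The file's checksum is
#' verified on load.
#'
#' @return list of class `contact_matrix_fixture` with `simulations`,
#'   `residues` and `values` (3 x 15 matrix of percentages).
#' @export
load_contact_fixture <- function() {
  path <- system.file("extdata", "table3_residue_contact_pct.tsv",
                      package = "pipbind", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), TABLE3_MD5)) {
    stop("integrity error: packaged contact-matrix fixture checksum mismatch",
         call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1])
  rownames(values) <- df$simulation
  if (any(values < 0 | values > 100)) {
    stop("integrity error: fixture percentages outside [0, 100]", call. = FALSE)
  }
  structure(list(simulations = df$simulation, residues = colnames(values),
                 values = values),
            class = "contact_matrix_fixture")
}

#' Load the packaged binding-site group definitions
#'
#' The two named residue groups used for pose classification: Group I (the
#' basic FERM F2 ridge plus the adjacent kinase C-lobe residues) and Group II
#' (the kinase N-/C-lobe interface residues), in FAK residue numbering.
#'
#' @return named list of [site_definition()] objects.
#' @export
load_site_groups <- function() {
  path <- system.file("extdata", "fak_site_groups.tsv",
                      package = "pipbind", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), SITES_MD5)) {
    stop("integrity error: packaged site-group fixture checksum mismatch",
         call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$group), function(g) {
    site_definition(g$group[1], residue_number(g$residue), labels = g$residue)
  })
  out[unique(df$group)]
}

# "K621" -> 621
residue_number <- function(labels) as.integer(sub("^[A-Za-z]+", "", labels))

#' Read coarse-grained bead coordinates from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb` for user-supplied structures: ATOM
#' records become beads (coordinates converted to nm), with chain and
#' insertion codes preserved as residue metadata. Only coordinates and
#' residue metadata are used; the rest of the PDB spec is out of scope.
#'
#' @param path PDB file.
#' @return list with `atoms` (residue_id, residue_name, bead_name, chain,
#'   insert) and `frame` (coordinates in nm; box = bounding box + 2 nm pad
#'   unless a CRYST1 record is present).
#' @export
read_pdb_beads <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_pdb_beads requires the 'bio3d' package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  xyz <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
  box <- NULL
  if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3 &&
      all(is.finite(pdb$cryst1$abc)) && all(pdb$cryst1$abc > 0)) {
    box <- pdb$cryst1$abc / 10
  }
  if (is.null(box)) {
    box <- apply(xyz, 2, function(v) diff(range(v))) + 2
  }
  xyz <- sweep(xyz, 2, apply(xyz, 2, min)) + 1  # keep coordinates positive
  list(
    atoms = data.frame(residue_id = a$resno, residue_name = a$resid,
                       bead_name = a$elety, chain = a$chain,
                       insert = a$insert, stringsAsFactors = FALSE),
    frame = frame(xyz, box, time = 0)
  )
}
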