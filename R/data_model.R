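#' Domain tables and validation
#'
#' The screening pipeline works on four plain data frames ("long" CSV
#' tables) plus a gapped DNA alignment:
#'
#' * `strains`: one row per strain with `strain_id`, `host_order`
#'   (closed vocabulary: Coleoptera, Diptera, Hemiptera, Hymenoptera,
#'   Lepidoptera, Orthoptera, or `"other"`), `host_species`, `state`
#'   and `source` (`cadaver`, `soil` or `plant`).
#' * `growth`: `strain_id`, `replicate`, `day` (1-15, days after
#'   inoculation), `diameter_a`, `diameter_b` -- the two perpendicular
#'   colony diameters in mm (0-90, the plate size).
#' * `spores`: `strain_id`, `replicate`, `day`, `conidia_conc`
#'   (x 10^8 conidia/ml, non-negative).
#' * `bioassay`: `strain_id` (or `"CONTROL"`), `replicate`,
#'   `day` (3, 5 or 7 days post spray), `n_marked`, `n_dead` --
#'   marked and dead nymph counts with `0 <= n_dead <= n_marked`.
#'
#' `validate_strains()` and friends check the invariants and fail with a
#' message naming the offending column or row.
#'
#' @param strains,growth,spores,bioassay data frames as described above.
#' @return The validated data frame, invisibly.
#' @name validate_tables
NULL

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), cols)
  if (length(extra) > 0L) {
    warning(sprintf("%s: ignoring unknown column(s): %s", what,
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  df[, cols, drop = FALSE]
}

#' @rdname validate_tables
#' @export
validate_strains <- function(strains) {
  strains <- .require_columns(
    strains, c("strain_id", "host_order", "host_species", "state", "source"),
    "strains")
  if (anyDuplicated(strains$strain_id)) {
    dup <- unique(strains$strain_id[duplicated(strains$strain_id)])
    stop("strains: duplicated strain_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- !(strains$host_order %in% .host_orders)
  if (any(bad)) {
    stop("strains: host_order outside the closed vocabulary at row(s) ",
         paste(which(bad), collapse = ", "), " (use \"other\")",
         call. = FALSE)
  }
  invisible(strains)
}

#' @rdname validate_tables
#' @export
validate_growth <- function(growth) {
  growth <- .require_columns(
    growth, c("strain_id", "replicate", "day", "diameter_a", "diameter_b"),
    "growth")
  if (nrow(growth) > 0L) {
    d <- c(growth$diameter_a, growth$diameter_b)
    if (any(!is.finite(d)) || any(d < 0) || any(d > 90)) {
      stop("growth: colony diameters must lie in [0, 90] mm", call. = FALSE)
    }
    if (any(growth$day < 1 | growth$day > 15)) {
      stop("growth: day must be in 1..15", call. = FALSE)
    }
    if (any(growth$replicate < 1)) {
      stop("growth: replicate index must be >= 1", call. = FALSE)
    }
  }
  invisible(growth)
}

#' @rdname validate_tables
#' @export
validate_spores <- function(spores) {
  spores <- .require_columns(
    spores, c("strain_id", "replicate", "day", "conidia_conc"), "spores")
  if (nrow(spores) > 0L && any(!is.finite(spores$conidia_conc) |
                               spores$conidia_conc < 0)) {
    stop("spores: conidia_conc must be finite and >= 0", call. = FALSE)
  }
  invisible(spores)
}

#' @rdname validate_tables
#' @export
validate_bioassay <- function(bioassay) {
  bioassay <- .require_columns(
    bioassay, c("strain_id", "replicate", "day", "n_marked", "n_dead"),
    "bioassay")
  if (nrow(bioassay) > 0L) {
    bad <- which(bioassay$n_dead > bioassay$n_marked |
                 bioassay$n_dead < 0 | bioassay$n_marked < 0)
    if (length(bad) > 0L) {
      stop("bioassay: n_dead outside [0, n_marked] at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!all(bioassay$day %in% c(3L, 5L, 7L))) {
      stop("bioassay: day must be one of 3, 5, 7", call. = FALSE)
    }
  }
  invisible(bioassay)
}

#' Read the measurement tables of a screening experiment
#'
#' Expects a directory with four comma-separated, UTF-8, one-header-row
#' files: `strains.csv`, `growth.csv`, `spores.csv` and `bioassay.csv`
#' (see [validate_tables] for their schemas). All invariants are checked
#' on read; unknown columns are dropped with a warning.
#'
#' @param path directory containing the four CSV files.
#' @return A list with elements `strains`, `growth`, `spores`,
#'   `bioassay` (validated data frames).
#' @export
read_measurements <- function(path) {
  files <- file.path(path, c("strains.csv", "growth.csv",
                             "spores.csv", "bioassay.csv"))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) {
    stop("read_measurements: file(s) not found: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rd <- function(f) read.csv(f, stringsAsFactors = FALSE)
  list(strains  = validate_strains(rd(files[1L])),
       growth   = validate_growth(rd(files[2L])),
       spores   = validate_spores(rd(files[3L])),
       bioassay = validate_bioassay(rd(files[4L])))
}

#' Write the measurement tables of a screening experiment
#'
#' @param panel a list with `strains`, `growth`, `spores`, `bioassay`
#'   (as from [generate_panel()] or [read_measurements()]).
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_measurements <- function(panel, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("strains", "growth", "spores", "bioassay")) {
    write.csv(panel[[nm]], file.path(path, paste0(nm, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# ---- alignments -----------------------------------------------------------

.iupac <- c("A", "C", "G", "T", "-", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

#' Construct a gapped DNA alignment
#'
#' An alignment is stored as a character matrix with one row per taxon
#' (rownames are the strain ids) and one column per aligned site.
#' IUPAC ambiguity codes and gaps (`-`) are retained; they are excluded
#' later, pair by pair, when distances are computed (pairwise deletion).
#'
#' @param seqs named character vector of equal-length sequence strings,
#'   or a character matrix of single residues with rownames.
#' @return An object of class `epf_alignment` (a character matrix).
#' @export
epf_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      off <- names(seqs)[lens != median(lens)]
      stop("alignment: unequal sequence lengths for taxa: ",
           paste(off, collapse = ", "), call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m))) stop("alignment: taxa must be named",
                                 call. = FALSE)
  if (anyDuplicated(rownames(m))) {
    stop("alignment: duplicate taxon labels: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(m) < 2L) stop("alignment: need >= 2 sequences", call. = FALSE)
  bad <- !(m %in% .iupac)
  if (any(bad)) {
    stop("alignment: non-IUPAC residue(s): ",
         paste(unique(m[bad]), collapse = ", "), call. = FALSE)
  }
  structure(m, class = "epf_alignment")
}

#' @export
print.epf_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d taxa x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read a pre-aligned FASTA file
#'
#' Sequences are uppercased; all must have equal length and unique
#' headers, and at least two records are required.
#'
#' @param path FASTA file of aligned sequences (gaps allowed).
#' @return An [epf_alignment()] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- ape::read.FASTA(path)
  if (length(dna) < 2L) stop("alignment: need >= 2 sequences", call. = FALSE)
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  epf_alignment(seqs)
}

#' Write an alignment as FASTA
#'
#' @param aln an [epf_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

# ---- strain summaries -----------------------------------------------------

#' Write and read strain summary tables
#'
#' A strain summary holds one row per strain: mycelial growth `MG` (mm),
#' sporulation `SP` (x 10^8 conidia/ml), corrected mortalities `MO3`,
#' `MO5`, `MO7` (%) and the bioefficacy index `BI` (%), plus the
#' virulence `category`. Values are written at one decimal, matching the
#' precision the index is reported at, so a write/read cycle is lossless
#' at that precision.
#'
#' @param summaries data frame with columns `strain_id`, `MG`, `SP`,
#'   `MO3`, `MO5`, `MO7`, `BI` and optionally `category`.
#' @param path CSV file path.
#' @return `write_summaries()` returns `path` invisibly;
#'   `read_summaries()` returns the data frame.
#' @export
write_summaries <- function(summaries, path) {
  cols <- c("MG", "SP", "MO3", "MO5", "MO7", "BI")
  out <- summaries
  for (cl in intersect(cols, names(out))) out[[cl]] <- round(out[[cl]], 1L)
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_summaries: cannot write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  mand <- c("strain_id", "MG", "SP", "MO3", "MO5", "MO7", "BI")
  keep <- c(mand, intersect("category", names(df)))
  .require_columns(df, keep, "summaries")
}
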