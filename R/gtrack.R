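#' Build a table of bead specifications
#'
#' A bead specification describes one TAD: its genomic interval (0-based
#' half-open), unique id, optional radius, lamina-periphery flag, and the
#' ids of contact partners. Homologous chromosome copies follow the
#' Chrom3D-style `"_A"`/`"_B"` suffix convention on the chromosome label.
#'
#' @param chrom Character chromosome labels.
#' @param start,end Integer-valued genomic coordinates in bp, `end > start`.
#' @param bead_id Unique character ids.
#' @param periphery Logical lamina-association flags.
#' @param edges List of character vectors of partner bead ids.
#' @param radius Optional numeric bead radii in micrometres (`NA` when
#'   radii are to be assigned from occupancy, see [assign_radii()]).
#' @return A `data.frame` of class `bead_specs`, edges symmetrized.
#' @export
bead_specs <- function(chrom, start, end, bead_id,
                       periphery = FALSE, edges = NULL, radius = NA_real_) {
  n <- length(chrom)
  if (is.null(edges)) edges <- rep(list(character(0)), n)
  specs <- data.frame(chrom = as.character(chrom),
                      start = as.numeric(start),
                      end = as.numeric(end),
                      bead_id = as.character(bead_id),
                      periphery = rep_len(as.logical(periphery), n),
                      radius = rep_len(as.numeric(radius), n),
                      stringsAsFactors = FALSE)
  specs$edges <- edges
  class(specs) <- c("bead_specs", "data.frame")
  validate_bead_specs(specs)
}

#' Validate and normalise a bead-specification table
#'
#' Checks interval sanity and id uniqueness, drops self-edges, reports
#' dangling edge partners, and symmetrizes the edge lists.
#'
#' @param specs A `bead_specs` data frame.
#' @return The validated table (edges symmetrized and sorted).
#' @export
validate_bead_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  need <- c("chrom", "start", "end", "bead_id", "periphery", "edges")
  miss <- setdiff(need, names(specs))
  if (length(miss)) stop("missing bead spec column(s): ",
                         paste(miss, collapse = ", "))
  bad <- specs$end <= specs$start
  if (any(bad)) {
    stop("invalid interval (end <= start) for bead(s): ",
         paste(utils::head(specs$bead_id[bad], 5), collapse = ", "))
  }
  if (anyDuplicated(specs$bead_id)) {
    stop("duplicated bead_id(s): ",
         paste(unique(specs$bead_id[duplicated(specs$bead_id)]), collapse = ", "))
  }
  if (!is.null(specs$radius) && any(!is.na(specs$radius) & specs$radius <= 0)) {
    stop("bead radius must be > 0")
  }
  ids <- specs$bead_id
  edges <- lapply(specs$edges, as.character)
  partners <- unique(unlist(edges, use.names = FALSE))
  dangling <- setdiff(partners, ids)
  if (length(dangling)) {
    stop("edge(s) reference unknown bead id(s): ",
         paste(dangling, collapse = ", "))
  }
  # symmetrize: if a lists b, b lists a; drop self edges; sort for stability
  idx <- seq_along(ids)
  names(idx) <- ids
  sym <- rep(list(character(0)), length(ids))
  for (i in idx) {
    for (p in setdiff(edges[[i]], ids[i])) {
      j <- idx[[p]]
      sym[[i]] <- c(sym[[i]], ids[j])
      sym[[j]] <- c(sym[[j]], ids[i])
    }
  }
  specs$edges <- lapply(sym, function(e) sort(unique(e)))
  class(specs) <- c("bead_specs", "data.frame")
  specs
}

gtrack_header_cols <- c("seqid", "start", "end", "id", "radius",
                        "periphery", "edges")

#' Read a Chrom3D-dialect gtrack file
#'
#' Lines starting `##` are metadata; the column header line starts `###`
#' and is tab-separated (`seqid start end id [radius] [periphery]
#' [edges]`). Edges are `;`-joined partner bead ids (an optional
#' `=weight` suffix per edge is read and ignored); `.` denotes an empty
#' field. Coordinates are interpreted as 0-based half-open. Edge lists
#' are symmetrized on load.
#'
#' @param path Path to a gtrack file.
#' @return A list with `specs` (a [bead_specs()] table) and `metadata`
#'   (character vector of `##` lines, without the prefix).
#' @export
read_gtrack <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  meta <- sub("^##\\s?", "", grep("^##[^#]", lines, value = TRUE))
  hdr_i <- grep("^###", lines)
  if (!length(hdr_i)) stop("gtrack format error: no '###' column header line")
  header <- strsplit(sub("^###", "", lines[hdr_i[1]]), "\t", fixed = TRUE)[[1]]
  header <- trimws(header)
  for (col in c("seqid", "start", "end", "id")) {
    if (!col %in% header) {
      stop("gtrack format error: missing mandatory column '", col, "'")
    }
  }
  data_lines <- lines[-seq_len(hdr_i[1])]
  data_lines <- data_lines[!grepl("^#", data_lines) & nzchar(trimws(data_lines))]
  if (!length(data_lines)) {
    return(list(specs = bead_specs(character(0), numeric(0), numeric(0),
                                   character(0)),
                metadata = meta))
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  get <- function(row, col) {
    j <- match(col, header)
    if (is.na(j) || j > length(row)) "." else row[[j]]
  }
  chrom <- vapply(fields, get, "", col = "seqid")
  start <- as.numeric(vapply(fields, get, "", col = "start"))
  end <- as.numeric(vapply(fields, get, "", col = "end"))
  id <- vapply(fields, get, "", col = "id")
  radius <- vapply(fields, get, "", col = "radius")
  radius <- ifelse(radius == ".", NA_real_, suppressWarnings(as.numeric(radius)))
  periphery <- vapply(fields, get, "", col = "periphery") == "1"
  edges <- lapply(vapply(fields, get, "", col = "edges"), function(e) {
    if (e == "." || !nzchar(e)) return(character(0))
    sub("=.*$", "", strsplit(e, ";", fixed = TRUE)[[1]])
  })
  specs <- bead_specs(chrom, start, end, id, periphery, edges, radius)
  list(specs = specs, metadata = meta)
}

#' Write a bead-specification table as a gtrack file
#'
#' Inverse of [read_gtrack()]: `read_gtrack(write_gtrack(x))` recovers
#' `x` on valid inputs.
#'
#' @param specs A [bead_specs()] table.
#' @param path Output path.
#' @param metadata Optional character vector of metadata lines.
#' @return `path`, invisibly.
#' @export
write_gtrack <- function(specs, path, metadata = character(0)) {
  specs <- validate_bead_specs(specs)
  fmt_num <- function(x) trimws(formatC(x, format = "g", digits = 17))
  rows <- if (nrow(specs)) {
    paste(specs$chrom,
          format(specs$start, scientific = FALSE, trim = TRUE),
          format(specs$end, scientific = FALSE, trim = TRUE),
          specs$bead_id,
          ifelse(is.na(specs$radius), ".", fmt_num(specs$radius)),
          ifelse(specs$periphery, "1", "."),
          vapply(specs$edges, function(e) {
            if (length(e)) paste(e, collapse = ";") else "."
          }, ""),
          sep = "\t")
  } else character(0)
  out <- c(if (length(metadata)) paste0("##", metadata),
           paste0("###", paste(gtrack_header_cols, collapse = "\t")),
           rows)
  writeLines(out, path)
  invisible(path)
}

#' Contact constraints from bead edges
#'
#' Deduplicates the symmetric edge lists into unordered bead-id pairs,
#' each of which the solver should bring spatially proximal.
#'
#' @param specs A [bead_specs()] table.
#' @return A `data.frame` with columns `bead_a`, `bead_b` (bead ids,
#'   `bead_a < bead_b`) — one row per unordered contact pair.
#' @export
contact_constraints <- function(specs) {
  specs <- validate_bead_specs(specs)
  from <- rep(specs$bead_id, lengths(specs$edges))
  to <- unlist(specs$edges, use.names = FALSE)
  if (!length(from)) {
    return(data.frame(bead_a = character(0), bead_b = character(0),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
  out <- data.frame(bead_a = a[keep], bead_b = b[keep],
                    stringsAsFactors = FALSE)
  out[order(out$bead_a, out$bead_b), , drop = FALSE]
}

#' Homolog key of a chromosome label
#'
#' Strips a trailing `"_A"`/`"_B"` homolog suffix, so the two copies of
#' a chromosome share one key. Used by the clustering homolog rule.
#'
#' @param chrom Character chromosome labels.
#' @return Character keys.
#' @examples
#' homolog_key(c("chr1_A", "chr1_B", "chrX"))
#' @export
homolog_key <- function(chrom) {
  sub("_[AB]$", "", as.character(chrom))
}
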