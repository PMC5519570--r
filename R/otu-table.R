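#' Construct an OTUTable
#'
#' @param counts numeric matrix of non-negative read counts, samples in rows
#'   and OTUs in columns, with dimnames.
#' @param taxonomy optional character vector of lineage strings, either named
#'   by OTU id or in column order.
#' @return An [OTUTable-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, dimnames = list(c("s1", "s2"), c("otuA", "otuB")))
#' OTUTable(m)
#' @export
OTUTable <- function(counts, taxonomy = character()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (length(taxonomy) && is.null(names(taxonomy))) {
    if (length(taxonomy) != ncol(counts))
      stop("unnamed taxonomy must have one entry per OTU")
    names(taxonomy) <- colnames(counts)
  }
  new("OTUTable", counts = counts, taxonomy = as.character(taxonomy))
}

#' @describeIn OTUTable read-count matrix (samples x OTUs)
#' @param object,x an OTUTable
#' @export
setMethod("counts", "OTUTable", function(object) object@counts)

#' @describeIn OTUTable sample identifiers
#' @export
setMethod("sampleIDs", "OTUTable", function(x) rownames(x@counts))

#' @describeIn OTUTable OTU identifiers
#' @export
setMethod("otuIDs", "OTUTable", function(x) colnames(x@counts))

#' @describeIn OTUTable per-OTU lineage strings (possibly empty)
#' @export
setMethod("taxonomy", "OTUTable", function(x) x@taxonomy)

#' @export
setMethod("dim", "OTUTable", function(x) dim(x@counts))

#' @param i,j sample / OTU indices (integer, logical or character)
#' @param ... ignored
#' @param drop ignored; subsetting always returns an OTUTable
#' @describeIn OTUTable subset samples (i) and OTUs (j)
#' @export
setMethod("[", "OTUTable", function(x, i, j, ..., drop = FALSE) {
  cts <- x@counts
  if (!missing(i)) cts <- cts[i, , drop = FALSE]
  if (!missing(j)) cts <- cts[, j, drop = FALSE]
  tax <- x@taxonomy
  if (length(tax)) tax <- tax[names(tax) %in% colnames(cts)]
  new("OTUTable", counts = cts, taxonomy = tax)
})

setMethod("show", "OTUTable", function(object) {
  cts <- object@counts
  cat(sprintf("OTUTable: %d samples x %d OTUs\n", nrow(cts), ncol(cts)))
  cat(sprintf("  total reads: %s; per-sample depth %s-%s\n",
              format(sum(cts), big.mark = ","),
              format(min(rowSums(cts)), big.mark = ","),
              format(max(rowSums(cts)), big.mark = ",")))
  if (length(object@taxonomy))
    cat(sprintf("  taxonomy for %d OTUs\n", length(object@taxonomy)))
  invisible(NULL)
})

# ---- I/O ---------------------------------------------------------------

#' Read / write OTU tables (TSV or BIOM-style JSON)
#'
#' TSV layout follows the common convention: rows are OTUs, columns are
#' samples, first column holds OTU ids, an optional final column `taxonomy`
#' holds lineage strings; leading `#`-prefixed provenance lines are skipped
#' (the header row itself may carry a leading `#OTU ID` as written by many
#' tools). BIOM input/output uses the JSON (BIOM 1.0) format via the
#' \pkg{biomformat} package.
#'
#' @param path file path.
#' @param format "auto" (by extension: .biom/.json vs anything else), "tsv" or
#'   "biom".
#' @return `readOTUTable` returns an [OTUTable-class]; `writeOTUTable`
#'   invisibly returns `path`.
#' @export
readOTUTable <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE)) "biom" else "tsv"
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # OTUs x samples
    tax <- character()
    om <- biomformat::observation_metadata(b)
    if (!is.null(om) && length(om)) {
      tax <- if (is.data.frame(om)) {
        apply(om, 1L, function(r) paste(r[!is.na(r)], collapse = "; "))
      } else {
        vapply(om, function(r) paste(unlist(r), collapse = "; "), character(1))
      }
      names(tax) <- rownames(m)
    }
    return(OTUTable(t(m), taxonomy = tax))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  is_comment <- startsWith(lines, "#") & !grepl("^#\\s*OTU", lines, ignore.case = TRUE)
  lines <- lines[!is_comment]
  if (!length(lines)) stop("no table content in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (length(unique(nfield)) != 1L)
    stop(sprintf("ragged TSV in %s: row %d has %d fields, expected %d",
                 path, which(nfield != nfield[1])[1], nfield[nfield != nfield[1]][1],
                 nfield[1]))
  header <- fields[[1]]
  has_tax <- tolower(header[length(header)]) %in% c("taxonomy", "consensus lineage")
  sample_ids <- header[-1]
  if (has_tax) sample_ids <- sample_ids[-length(sample_ids)]
  body <- fields[-1]
  otu_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id in ", path, ": ", otu_ids[duplicated(otu_ids)][1])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in ", path, ": ", sample_ids[duplicated(sample_ids)][1])
  ncts <- length(sample_ids)
  cts <- matrix(0, nrow = length(otu_ids), ncol = ncts,
                dimnames = list(otu_ids, sample_ids))
  tax <- character()
  for (k in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[k]][2:(1 + ncts)]))
    if (anyNA(vals))
      stop(sprintf("non-numeric count in %s, OTU row '%s'", path, otu_ids[k]))
    if (any(vals < 0))
      stop(sprintf("negative count in %s, OTU row '%s'", path, otu_ids[k]))
    cts[k, ] <- vals
  }
  if (has_tax) {
    tax <- vapply(body, function(f) f[[length(f)]], character(1))
    names(tax) <- otu_ids
  }
  OTUTable(t(cts), taxonomy = tax)
}

#' @rdname readOTUTable
#' @param x an [OTUTable-class]
#' @param provenance optional character scalar written as a leading `#` comment
#'   line (tool version, seed, parameters) on TSV output.
#' @export
writeOTUTable <- function(x, path, format = c("auto", "tsv", "biom"),
                          provenance = NULL) {
  stopifnot(is(x, "OTUTable"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE)) "biom" else "tsv"
  cts <- t(x@counts)  # OTUs x samples on disk
  if (format == "biom") {
    om <- NULL
    if (length(x@taxonomy))
      om <- data.frame(taxonomy = unname(x@taxonomy[rownames(cts)]),
                       row.names = rownames(cts))
    b <- biomformat::make_biom(cts, observation_metadata = om)
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  has_tax <- length(x@taxonomy) > 0
  header <- c("#OTU ID", colnames(cts), if (has_tax) "taxonomy")
  writeLines(paste(header, collapse = "\t"), con)
  tax <- if (has_tax) x@taxonomy[rownames(cts)] else NULL
  body <- vapply(seq_len(nrow(cts)), function(k) {
    paste(c(rownames(cts)[k], format(cts[k, ], scientific = FALSE, trim = TRUE),
            if (has_tax) tax[k]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Metadata arrives as a TSV with the required columns `sample_id`,
#' `population`, `deme`, `sample_type` (animal|water), `latitude`,
#' `longitude`, `elevation`, `forest_cover`.
#'
#' @param path file path
#' @return data.frame with the required columns.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample_id", "population", "deme", "sample_type",
           "latitude", "longitude", "elevation", "forest_cover")
  miss <- setdiff(req, names(md))
  if (length(miss))
    stop("metadata is missing required columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(md$sample_type), c("animal", "water"))
  if (length(bad))
    stop("sample_type must be 'animal' or 'water'; found: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata")
  md
}

#' Read / write a square labelled distance matrix as TSV
#'
#' Square TSV with an id header row and an id first column, as used for Fst
#' and for exported UniFrac/Jaccard matrices.
#'
#' @param path file path
#' @param m square symmetric matrix with dimnames
#' @export
readDistanceTSV <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE,
                                   comment.char = "#"))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("not a square labelled matrix: ", path)
  if (max(abs(m - t(m))) > 1e-8) stop("matrix is not symmetric: ", path)
  m
}

#' @rdname readDistanceTSV
#' @export
writeDistanceTSV <- function(m, path) {
  m <- as.matrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
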