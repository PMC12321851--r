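# Readers and writers: TSV abundance tables (tab-separated, UTF-8, '#'
# comments ignored, first column = id), optional BIOM input, and network
# exports (edge-list TSV + GraphML for Cytoscape import).

#' Read an abundance table
#'
#' TSV dialect: tab-separated, `#` comment lines ignored, first column holds
#' ids. Canonical orientation is samples in rows. With
#' `orientation = "auto"` the header of the id column decides: names matching
#' sample-like keywords (`sample`, `sampleid`, `#SampleID`) keep rows as
#' samples; feature-like keywords (`taxon`, `genus`, `feature`, `pathway`,
#' `#OTU ID`) transpose, as in pathway prediction output shipped pathways x
#' samples. Anything else is treated as samples-in-rows. Duplicate ids,
#' ragged rows, non-numeric or negative entries are errors naming the
#' offending location.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"` (requires the biomformat package).
#' @param counts logical; when TRUE, rows are closed to relative abundances
#'   summing to 1.
#' @param orientation `"auto"`, `"samples"` (rows are samples) or
#'   `"features"` (rows are features; table is transposed).
#' @return samples x features numeric matrix with an `orientation` attribute
#'   describing what was detected.
#' @export
read_abundance <- function(path, format = c("tsv", "biom"), counts = FALSE,
                           orientation = c("auto", "samples", "features")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM requires the biomformat package")
    }
    bm <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(bm)))  # biom stores features x samples
    detected <- "samples"  # already transposed to the canonical orientation
  } else {
    df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            header = TRUE)
    if (ncol(df) < 2) stop("abundance table needs an id column plus data columns")
    id_name <- names(df)[1L]
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) {
      stop("duplicate ids in first column: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      conv <- suppressWarnings(
        matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m)))
      if (anyNA(conv) && !all(is.na(m) == is.na(conv))) {
        bad <- which(is.na(conv) & !is.na(m), arr.ind = TRUE)
        stop(sprintf("non-numeric value at row '%s', column '%s'",
                     ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
      }
      m <- conv
    }
    rownames(m) <- ids
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      stop(sprintf("negative value at row '%s', column '%s'",
                   rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]))
    }
    detected <- if (orientation != "auto") orientation else {
      key <- tolower(gsub("[^a-z]", "", tolower(id_name)))
      if (grepl("sample", key)) "samples"
      else if (grepl("taxon|genus|feature|otu|pathway|pwy", key)) "features"
      else "samples"
    }
  }
  if (detected == "features") m <- t(m)
  if (counts) {
    rs <- rowSums(m)
    if (any(rs == 0)) stop("cannot close samples with zero total counts: ",
                           paste(rownames(m)[rs == 0], collapse = ", "))
    m <- m / rs
  }
  attr(m, "orientation") <- detected
  m
}

#' Write an abundance table as TSV
#'
#' Samples in rows, first column `sample_id`, tab-separated.
#'
#' @param x samples x features matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_abundance <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metadata table
#'
#' TSV with a `sample_id` first column; all other columns kept as-is.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df
}

#' Export a co-abundance network
#'
#' Writes the edge list as TSV (`source`, `target`, `rho`, `p`, `q`,
#' `cag_source`, `cag_target` when a partition is supplied) and optionally a
#' GraphML file for Cytoscape import.
#'
#' @param net a [build_network()] or [genus_pathway_network()] result.
#' @param edge_path TSV output path.
#' @param graphml_path optional GraphML output path.
#' @param partition optional [cluster_cags()] result used to annotate nodes.
#' @return invisibly, the paths written.
#' @export
export_network <- function(net, edge_path, graphml_path = NULL,
                           partition = NULL) {
  if (inherits(net, "cag_network")) {
    edges <- net$edges
    names(edges)[1:2] <- c("source", "target")
  } else if (inherits(net, "cag_bipartite")) {
    edges <- net$edges
    names(edges)[1:2] <- c("source", "target")
  } else stop("unsupported network object")
  if (!is.null(partition)) {
    lookup <- function(g) {
      cid <- partition$assignment[g]
      ifelse(is.na(cid), "", sprintf("CAG%d", cid))
    }
    edges$cag_source <- lookup(edges$source)
    edges$cag_target <- lookup(edges$target)
  }
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- edge_path
  if (!is.null(graphml_path)) {
    if (nrow(edges)) {
      g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    } else {
      g <- igraph::make_empty_graph(directed = FALSE)
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
    paths <- c(paths, graphml_path)
  }
  invisible(paths)
}

# Quiet TSV writer for report data frames.
write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
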