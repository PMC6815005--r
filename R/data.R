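# Association tables, disease DAG files, and the bipartite adjacency matrix.

#' Construct an association dataset from a table of (disease, metabolite) pairs
#'
#' The dataset holds the deduplicated pair set together with the 0/1 adjacency
#' matrix `M` (diseases in rows, metabolites in columns). Row and column
#' ordering follow first appearance in `pairs`, so loading the same file twice
#' yields identical index maps. Every identifier must occur in at least one
#' pair: the node universes are defined by the pair set itself, mirroring a
#' curated association snapshot in which every disease and metabolite carries
#' at least one known association.
#'
#' @param pairs data.frame with character columns `disease_id`,
#'   `metabolite_id`; whitespace is stripped, ids compared case-sensitively.
#' @return An object of class `association_dataset`: a list with
#'   `disease_ids`, `metabolite_ids`, `pairs` (deduplicated data.frame) and
#'   `M` (0/1 matrix, `n_d x n_m`, dimnames set to the ids).
#' @export
association_dataset <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) {
    stop("association dataset must contain at least one pair")
  }
  d <- trimws(as.character(pairs[[1L]]))
  m <- trimws(as.character(pairs[[2L]]))
  if (any(d == "") || any(m == "")) {
    stop("empty identifier in association pairs")
  }
  key <- paste(d, m, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate association pair(s) dropped")
    d <- d[!dup]
    m <- m[!dup]
  }
  disease_ids <- unique(d)
  metabolite_ids <- unique(m)
  M <- matrix(0L, nrow = length(disease_ids), ncol = length(metabolite_ids),
              dimnames = list(disease_ids, metabolite_ids))
  M[cbind(match(d, disease_ids), match(m, metabolite_ids))] <- 1L
  structure(
    list(disease_ids = disease_ids,
         metabolite_ids = metabolite_ids,
         pairs = data.frame(disease_id = d, metabolite_id = m,
                            stringsAsFactors = FALSE),
         M = M),
    class = "association_dataset")
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf("<association_dataset> %d diseases x %d metabolites, %d pairs\n",
              length(x$disease_ids), length(x$metabolite_ids), nrow(x$pairs)))
  invisible(x)
}

.assoc_sep <- function(dialect) switch(match.arg(dialect, c("csv", "tsv")),
                                       csv = ",", tsv = "\t")

#' Read a two-column metabolite-disease association table
#'
#' Expects one pair per row, columns `disease_id,metabolite_id`. Rows with a
#' field count other than two raise an error naming the offending line;
#' duplicated pairs are dropped with a warning.
#'
#' @param path path to a CSV/TSV file.
#' @param dialect `"csv"` (comma) or `"tsv"` (tab).
#' @param header logical; if `TRUE` the first line is skipped.
#' @return An [association_dataset()].
#' @export
load_associations <- function(path, dialect = c("csv", "tsv"), header = FALSE) {
  sep <- .assoc_sep(dialect)
  if (!file.exists(path)) stop("association file not found: ", path)
  nf <- count.fields(path, sep = sep, comment.char = "", quote = "\"",
                     blank.lines.skip = TRUE)
  if (length(nf) == 0L) stop("association file is empty: ", path)
  body <- if (header) nf[-1L] else nf
  if (header && length(body) == 0L) stop("association file has no data rows: ", path)
  bad <- which(body != 2L)
  if (length(bad)) {
    stop(sprintf("malformed row in %s at line %d: expected 2 fields, found %d",
                 path, bad[1L] + as.integer(header), body[bad[1L]]))
  }
  tab <- read.table(path, sep = sep, header = header, colClasses = "character",
                    comment.char = "", quote = "\"", blank.lines.skip = TRUE,
                    stringsAsFactors = FALSE)
  names(tab) <- c("disease_id", "metabolite_id")
  association_dataset(tab)
}

#' Write an association dataset back to a two-column table
#'
#' @param dataset an [association_dataset()].
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param header write a `disease_id,metabolite_id` header line?
#' @return `path`, invisibly.
#' @export
write_associations <- function(dataset, path, dialect = c("csv", "tsv"),
                               header = FALSE) {
  stopifnot(inherits(dataset, "association_dataset"))
  write.table(dataset$pairs, path, sep = .assoc_sep(dialect),
              row.names = FALSE, col.names = header, quote = FALSE)
  invisible(path)
}

#' Construct a disease DAG (the disease plus its ancestor terms)
#'
#' A disease DAG holds the disease term itself together with all of its
#' ancestors, and directed edges from each more general term (parent) to the
#' more specific term (child). Acyclicity is verified with igraph.
#'
#' @param disease_id identifier of the disease at the bottom of the DAG.
#' @param nodes character vector of term ids; must contain `disease_id`.
#' @param edges data.frame with columns `parent`, `child` (may have 0 rows).
#' @return An object of class `disease_dag`.
#' @export
disease_dag <- function(disease_id, nodes, edges = NULL) {
  disease_id <- trimws(disease_id)
  nodes <- unique(trimws(as.character(nodes)))
  if (is.null(edges)) {
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- data.frame(parent = trimws(as.character(edges[[1L]])),
                      child = trimws(as.character(edges[[2L]])),
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$parent, edges$child, sep = "\r")), ,
                 drop = FALSE]
  if (!(disease_id %in% nodes)) {
    stop("disease ", disease_id, " is not among its own DAG nodes")
  }
  ep <- unique(c(edges$parent, edges$child))
  if (!all(ep %in% nodes)) {
    stop("edge endpoint(s) not in node set for disease ", disease_id, ": ",
         paste(setdiff(ep, nodes), collapse = ", "))
  }
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = nodes))
    if (!igraph::is_dag(g)) {
      stop("cycle detected in DAG of disease ", disease_id)
    }
  }
  structure(list(disease_id = disease_id, nodes = nodes, edges = edges),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> %s: %d terms, %d edges\n",
              x$disease_id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a file of per-disease DAG edge lists
#'
#' Format: one row per edge, columns `disease_id,parent_term,child_term`.
#' A disease with no ancestors is declared by a single row whose parent and
#' child both equal the disease term itself (a self-row adds the node but no
#' edge). Each disease's graph is cycle-checked; a cycle raises an error
#' naming the disease.
#'
#' @inheritParams load_associations
#' @return Named list mapping `disease_id` to [disease_dag()] objects.
#' @export
load_dags <- function(path, dialect = c("csv", "tsv"), header = FALSE) {
  sep <- .assoc_sep(dialect)
  if (!file.exists(path)) stop("DAG file not found: ", path)
  nf <- count.fields(path, sep = sep, comment.char = "", quote = "\"",
                     blank.lines.skip = TRUE)
  if (length(nf) == 0L) stop("DAG file is empty: ", path)
  body <- if (header) nf[-1L] else nf
  bad <- which(body != 3L)
  if (length(bad)) {
    stop(sprintf("malformed row in %s at line %d: expected 3 fields, found %d",
                 path, bad[1L] + as.integer(header), body[bad[1L]]))
  }
  tab <- read.table(path, sep = sep, header = header, colClasses = "character",
                    comment.char = "", quote = "\"", blank.lines.skip = TRUE,
                    stringsAsFactors = FALSE)
  names(tab) <- c("disease_id", "parent", "child")
  tab[] <- lapply(tab, trimws)
  out <- lapply(split(tab, factor(tab$disease_id, levels = unique(tab$disease_id))),
                function(rows) {
    self <- rows$parent == rows$child
    nodes <- unique(c(rows$disease_id[1L], rows$parent, rows$child))
    disease_dag(rows$disease_id[1L], nodes,
                rows[!self, c("parent", "child"), drop = FALSE])
  })
  out
}

#' Write DAGs in the edge-list dialect read by [load_dags()]
#'
#' @param dags named list of [disease_dag()] objects.
#' @inheritParams write_associations
#' @return `path`, invisibly.
#' @export
write_dags <- function(dags, path, dialect = c("csv", "tsv")) {
  rows <- do.call(rbind, lapply(dags, function(dag) {
    if (nrow(dag$edges) == 0L) {
      data.frame(disease_id = dag$disease_id, parent = dag$disease_id,
                 child = dag$disease_id, stringsAsFactors = FALSE)
    } else {
      data.frame(disease_id = dag$disease_id, parent = dag$edges$parent,
                 child = dag$edges$child, stringsAsFactors = FALSE)
    }
  }))
  write.table(rows, path, sep = .assoc_sep(dialect),
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the 0/1 adjacency matrix of an association dataset
#'
#' `M[i, j] = 1` iff disease `i` is known to be associated with metabolite
#' `j`; the sum of all entries equals the number of known pairs.
#'
#' @param dataset an [association_dataset()].
#' @return Integer 0/1 matrix, diseases in rows, metabolites in columns.
#' @export
adjacency <- function(dataset) {
  stopifnot(inherits(dataset, "association_dataset"))
  M <- dataset$M
  stopifnot(sum(M) == nrow(dataset$pairs))
  M
}

#' Paths of the bundled toy fixture (synthetic)
#'
#' A small synthetic benchmark shipped with the package: 20 diseases x 60
#' metabolites with 150 association pairs and a matching DAG forest, generated
#' by [synth_generate()] with a fixed seed. Useful for examples and smoke
#' tests without any download.
#'
#' @return Named list with elements `associations` and `dags` (file paths).
#' @export
toy_fixture_paths <- function() {
  list(
    associations = system.file("extdata", "toy_associations_synthetic.csv",
                               package = "katzmda", mustWork = TRUE),
    dags = system.file("extdata", "toy_dags_synthetic.csv",
                       package = "katzmda", mustWork = TRUE))
}
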