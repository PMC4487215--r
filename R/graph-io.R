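#' Construct a PPI network from an edge table
#'
#' Builds an undirected, simple protein-protein interaction network from a
#' two-column table of interacting protein identifiers. Self-interactions and
#' repeated interactions (in either orientation) are removed, matching the
#' hygiene applied to curated PPI datasets before alignment.
#'
#' @param edges A data frame whose first two columns name the interacting
#'   proteins. Extra columns are ignored. Protein identifiers are treated as
#'   case-sensitive opaque strings.
#' @param species_label Character scalar naming the species/network; carried
#'   through to downstream results.
#' @param nodes Optional character vector of additional protein identifiers to
#'   include as (possibly isolated) nodes.
#'
#' @return A `ppi_network` object: an undirected simple [igraph][igraph::graph]
#'   graph plus a species label.
#' @examples
#' net <- ppi_network(data.frame(a = c("a", "b", "a"), b = c("b", "a", "a")), "toy")
#' network_size(net)
#' @export
ppi_network <- function(edges, species_label = "network", nodes = NULL) {
  stopifnot(is.character(species_label), length(species_label) == 1L)
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (!is.null(nodes) && length(nodes)) {
      g <- igraph::add_vertices(g, length(unique(nodes)),
                                name = unique(as.character(nodes)))
    }
  } else {
    edges <- as.data.frame(edges)
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    # collapse duplicates irrespective of column order
    lo <- pmin(a, b); hi <- pmax(a, b)
    dup <- duplicated(paste(lo, hi, sep = "\r"))
    lo <- lo[!dup]; hi <- hi[!dup]
    verts <- unique(c(lo, hi, as.character(nodes %||% character())))
    g <- igraph::graph_from_data_frame(
      data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = verts, stringsAsFactors = FALSE)
    )
  }
  structure(list(graph = g, species = species_label), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network '%s': %d proteins, %d interactions>\n",
              x$species, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node and edge accessors for PPI networks
#'
#' @param net A `ppi_network`.
#' @return `network_nodes()` returns the character vector of protein IDs;
#'   `network_size()` a named vector with node and edge counts.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  as.character(igraph::V(net$graph)$name %||% character())
}

#' @rdname network_nodes
#' @export
network_size <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  c(nodes = igraph::vcount(net$graph), edges = igraph::ecount(net$graph))
}

#' @exportS3Method tibble::as_tibble
as_tibble.ppi_network <- function(x, ...) {
  if (igraph::ecount(x$graph) == 0L) {
    return(tibble::tibble(protein_a = character(), protein_b = character()))
  }
  el <- igraph::as_edgelist(x$graph, names = TRUE)
  tibble::tibble(protein_a = el[, 1L], protein_b = el[, 2L])
}

#' Read a PPI network from a tab-delimited edge list
#'
#' Each non-comment line names one interaction: two whitespace- or
#' tab-separated protein identifiers (extra columns, e.g. confidence scores,
#' are ignored). Lines starting with `#` are comments. Self-interactions and
#' repeated interactions are dropped, and the number of dropped records is
#' reported via a message.
#'
#' @param path Path to the edge-list file.
#' @param species_label Species/network label stored on the result.
#' @return A [ppi_network].
#' @export
read_ppi_network <- function(path, species_label = basename(path)) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (length(body) == 0L) {
    return(ppi_network(NULL, species_label))
  }
  toks <- strsplit(trimws(body), "[ \t]+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("line %d of '%s' has fewer than 2 fields",
                 which(keep)[bad[1L]], path))
  }
  a <- vapply(toks, `[[`, "", 1L)
  b <- vapply(toks, `[[`, "", 2L)
  net <- ppi_network(data.frame(a = a, b = b, stringsAsFactors = FALSE),
                     species_label)
  dropped <- length(a) - unname(network_size(net)["edges"])
  if (dropped > 0L) {
    message(sprintf("read_ppi_network: dropped %d self-loop/duplicate record(s) from '%s'",
                    dropped, path))
  }
  net
}

#' Write a PPI network as a tab-delimited edge list
#'
#' @param net A [ppi_network].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ppi_network <- function(net, path) {
  tb <- as_tibble.ppi_network(net)
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a protein complex catalogue
#'
#' Flat catalogue format: one complex per line, members separated by
#' whitespace or tabs. When `id_column = TRUE` the first token of each line is
#' taken as the complex identifier; otherwise complexes are numbered in file
#' order. Duplicate members within a line are collapsed; blank lines and
#' complexes left empty after deduplication are skipped with a warning.
#'
#' @param path Path to the catalogue file.
#' @param id_column Does the first column hold a complex ID?
#' @return A tibble with columns `complex_id` (character) and `members`
#'   (list of character vectors), in file order.
#' @export
read_complexes <- function(path, id_column = TRUE) {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[!grepl("^\\s*#", lines)]
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning(sprintf("read_complexes: skipped %d blank line(s) in '%s'",
                    sum(blank), path))
  }
  lines <- lines[!blank]
  toks <- strsplit(trimws(lines), "[ \t]+")
  ids <- character(length(toks))
  members <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (id_column) {
      ids[i] <- tk[1L]
      members[[i]] <- unique(tk[-1L])
    } else {
      ids[i] <- sprintf("C%d", i)
      members[[i]] <- unique(tk)
    }
  }
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning(sprintf("read_complexes: dropped %d complex(es) with no members",
                    sum(empty)))
  }
  tibble::tibble(complex_id = ids[!empty], members = members[!empty])
}

#' Write a protein complex catalogue
#'
#' @param catalogue Tibble with `complex_id` and `members` columns, as
#'   produced by [read_complexes()].
#' @param path Output path.
#' @param id_column Write the complex ID as the first column?
#' @return `path`, invisibly.
#' @export
write_complexes <- function(catalogue, path, id_column = TRUE) {
  lines <- vapply(seq_len(nrow(catalogue)), function(i) {
    mem <- paste(catalogue$members[[i]], collapse = "\t")
    if (id_column) paste(catalogue$complex_id[i], mem, sep = "\t") else mem
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write and read conserved-solution tables
#'
#' Solutions are serialised one per row as TSV with columns `solution_id`,
#' `members_one` (comma-joined), `members_two` (comma-joined) and `links`
#' (comma-joined `a:b` pairs). A write/read round trip is the identity on the
#' member and link sets.
#'
#' @param solutions A solutions tibble (see [align_networks()]) with list
#'   columns `members_one`, `members_two` and `links` (two-column character
#'   matrices or data frames).
#' @param path File path.
#' @return `write_solutions()` returns `path` invisibly; `read_solutions()`
#'   returns a solutions tibble.
#' @export
write_solutions <- function(solutions, path) {
  header <- "solution_id\tmembers_one\tmembers_two\tlinks"
  if (is.null(solutions) || nrow(solutions) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  has_links <- "links" %in% names(solutions)
  rows <- vapply(seq_len(nrow(solutions)), function(i) {
    lk <- if (has_links) solutions$links[[i]] else NULL
    lk_str <- if (is.null(lk) || nrow(lk) == 0L) "" else
      paste(paste(lk[, 1L], lk[, 2L], sep = ":"), collapse = ",")
    paste(solutions$solution_id[i],
          paste(sort(solutions$members_one[[i]]), collapse = ","),
          paste(sort(solutions$members_two[[i]]), collapse = ","),
          lk_str, sep = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_solutions
#' @export
read_solutions <- function(path) {
  lines <- readLines(path)
  if (length(lines) <= 1L) {
    return(tibble::tibble(solution_id = character(),
                          members_one = list(), members_two = list(),
                          links = list()))
  }
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  split_csv <- function(x) if (is.na(x) || !nzchar(x)) character() else
    strsplit(x, ",", fixed = TRUE)[[1L]]
  tibble::tibble(
    solution_id = vapply(parts, `[`, "", 1L),
    members_one = lapply(parts, function(p) split_csv(p[2L])),
    members_two = lapply(parts, function(p) split_csv(p[3L])),
    links = lapply(parts, function(p) {
      pr <- split_csv(if (length(p) >= 4L) p[4L] else "")
      if (!length(pr)) return(matrix(character(), 0L, 2L))
      m <- do.call(rbind, strsplit(pr, ":", fixed = TRUE))
      m
    })
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
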