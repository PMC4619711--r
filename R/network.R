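NODE_COLORS <- c(gene = "green", drug = "blue", category = "yellow")

#' Build the tri-partite gene-drug-category interaction network
#'
#' Nodes are genes, drugs and drug functional categories; a directed
#' gene->drug edge exists iff some (optionally: matched) annotation links a
#' variant of that gene to that drug, and a drug->category edge iff the
#' drug's record lists that category. Isolated nodes are omitted. Node color
#' attributes follow the usual rendering convention (gene green, drug blue,
#' category yellow).
#'
#' @param kb A [pgx_kb] object.
#' @param matches Optional matched-annotation tibble (from
#'   [annotate_sample()]); when given, the network is restricted to the
#'   sample's matched gene-drug pairs (a personal network), otherwise the
#'   whole knowledge base is used.
#' @return An igraph graph (class `pgx_network`/`igraph`) with vertex
#'   attributes `name`, `node_type`, `color` and edge attribute `edge_type`
#'   (`"gene_drug"` or `"drug_category"`). Gene->drug edges also carry the
#'   set of effect directions seen for that pair (`directions` attribute).
#' @examples
#' net <- build_network(mini_kb())
#' igraph::degree(net, "warfarin", mode = "in")
#' @export
build_network <- function(kb, matches = NULL) {
  stopifnot(inherits(kb, "pgx_kb"))
  ann <- if (is.null(matches)) kb$annotations else {
    kb$annotations |>
      dplyr::semi_join(matches, by = c("rsid", "genotype", "gene", "drug"))
  }

  gd <- ann |>
    dplyr::group_by(.data$gene, .data$drug) |>
    dplyr::summarise(
      directions = paste(sort(unique(.data$direction)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene, .data$drug)

  dc <- kb$drugs |>
    dplyr::filter(.data$drug %in% gd$drug) |>
    dplyr::select("drug", "categories") |>
    tidyr::unnest_longer("categories", values_to = "category") |>
    dplyr::mutate(category = as.character(.data$category)) |>
    dplyr::filter(!is.na(.data$category), nzchar(.data$category)) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$drug, .data$category)

  cats <- unique(as.character(dc$category))
  nodes <- dplyr::bind_rows(
    tibble::tibble(name = unique(gd$gene), node_type = "gene"),
    tibble::tibble(name = unique(gd$drug), node_type = "drug"),
    tibble::tibble(name = cats[!is.na(cats)], node_type = "category")
  )
  # a name appearing as two types (e.g. a drug named like a gene) is rejected
  if (anyDuplicated(nodes$name)) {
    stop_pgx("node names collide across types; rename the offending entity",
             class = "pgx_input_error")
  }
  edges <- dplyr::bind_rows(
    tibble::tibble(from = gd$gene, to = gd$drug, edge_type = "gene_drug",
                   directions = gd$directions),
    tibble::tibble(from = dc$drug, to = dc$category,
                   edge_type = "drug_category", directions = NA_character_)
  )

  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  igraph::V(g)$color <- unname(NODE_COLORS[igraph::V(g)$node_type])
  class(g) <- c("pgx_network", class(g))
  g
}

#' Export a network to GraphML, JSON node-link, or Graphviz DOT
#'
#' GraphML preserves the typed attributes and round-trips through
#' [import_network()] to a typed-isomorphic graph.
#'
#' @param net A network from [build_network()].
#' @param path Output file path.
#' @param format `"graphml"`, `"json"` or `"dot"`.
#' @param directed Write a directed graph (default); `FALSE` collapses to
#'   undirected before export.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("graphml", "json", "dot"),
                           directed = TRUE) {
  format <- match.arg(format)
  g <- net
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  if (format == "json") {
    nodes <- tibble::tibble(id = igraph::V(g)$name,
                            node_type = igraph::V(g)$node_type)
    ed <- igraph::as_data_frame(g, what = "edges")
    jsonlite::write_json(
      list(directed = directed, nodes = nodes,
           links = tibble::tibble(source = ed$from, target = ed$to,
                                  edge_type = ed$edge_type)),
      path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  } else {
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' @rdname export_network
#' @return `import_network()`: the graph re-read from a GraphML file, with
#'   `node_type`/`color` vertex attributes intact.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  # igraph stores the exported name under "name"; keep classes consistent
  class(g) <- c("pgx_network", class(g))
  g
}

#' @export
print.pgx_network <- function(x, ...) {
  tt <- table(igraph::V(x)$node_type)
  cat(sprintf("<pgx_network> %d nodes (%s), %d edges\n",
              igraph::vcount(x),
              paste(sprintf("%s: %d", names(tt), tt), collapse = ", "),
              igraph::ecount(x)))
  invisible(x)
}

#' @method tidy pgx_network
#' @export
tidy.pgx_network <- function(x, ...) {
  ed <- igraph::as_data_frame(x, what = "edges")
  tibble::as_tibble(ed) |>
    dplyr::rename(from_node = "from", to_node = "to")
}

#' @method glance pgx_network
#' @export
glance.pgx_network <- function(x, ...) {
  types <- igraph::V(x)$node_type
  tibble::tibble(
    n_nodes = igraph::vcount(x),
    n_genes = sum(types == "gene"),
    n_drugs = sum(types == "drug"),
    n_categories = sum(types == "category"),
    n_edges = igraph::ecount(x)
  )
}

#' Plot a gene-drug-category network
#'
#' A minimal ggplot2 rendering with the conventional colors (gene green,
#' drug blue, category yellow) and a deterministic force-directed layout.
#'
#' @param object A network from [build_network()].
#' @param seed Layout seed, for reproducible figures.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pgx_network
#' @export
autoplot.pgx_network <- function(object, seed = 1L, ...) {
  set.seed(seed)
  xy <- igraph::layout_with_fr(object)
  nodes <- tibble::tibble(
    name = igraph::V(object)$name,
    node_type = igraph::V(object)$node_type,
    x = xy[, 1], y = xy[, 2]
  )
  ed <- igraph::as_data_frame(object, what = "edges")
  seg <- tibble::tibble(
    x = nodes$x[match(ed$from, nodes$name)],
    y = nodes$y[match(ed$from, nodes$name)],
    xend = nodes$x[match(ed$to, nodes$name)],
    yend = nodes$y[match(ed$to, nodes$name)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      color = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$node_type),
      shape = 21, size = 5) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -1.2, size = 3) +
    ggplot2::scale_fill_manual(values = NODE_COLORS, name = "type") +
    ggplot2::theme_void()
}

#' @rdname autoplot.pgx_network
#' @param net A network from [build_network()].
#' @export
plot_network <- function(net, seed = 1L) autoplot.pgx_network(net, seed)
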