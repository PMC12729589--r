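#' Assemble the ceRNA network
#'
#' Builds the bipartite-plus-pair graph from screened ceRNA pairs and
#' retained miRNA-ceRNA edges. RNA nodes are the pair members; miRNA nodes
#' are the miRNAs with a retained edge to at least one RNA node. The
#' connectivity of an RNA node is the number of distinct miRNAs with
#' retained targeting edges to it; a miRNA's connectivity is its number of
#' distinct RNA neighbours.
#'
#' @param pairs screened pairs from [screen_pairs()].
#' @param edges retained edges from [spearman_edges()].
#' @return An object of class `cerna_network`: list with `nodes` (tibble
#'   `id`, `type`, `connectivity`) and `edges` (tibble `from`, `to`,
#'   `edge_type` in mirna-cerna / cerna-cerna, `rho`, `pearson_r`,
#'   `hyper_p`, `k`).
#' @export
build_network <- function(pairs, edges) {
  rna_ids <- sort(unique(c(pairs$rna_a, pairs$rna_b)))
  mir_edges <- edges |>
    filter(.data$cerna_id %in% rna_ids) |>
    distinct(.data$mirna_id, .data$cerna_id, .keep_all = TRUE)
  net_edges <- bind_rows(
    tibble(
      from = mir_edges$mirna_id, to = mir_edges$cerna_id,
      edge_type = "mirna-cerna", rho = mir_edges$rho,
      pearson_r = NA_real_, hyper_p = NA_real_, k = NA_integer_
    ),
    tibble(
      from = pairs$rna_a, to = pairs$rna_b,
      edge_type = "cerna-cerna", rho = NA_real_,
      pearson_r = pairs$pearson_r, hyper_p = pairs$hyper_p,
      k = as.integer(pairs$k)
    )
  )
  rna_conn <- mir_edges |>
    group_by(id = .data$cerna_id) |>
    summarise(connectivity = dplyr::n_distinct(.data$mirna_id), .groups = "drop")
  mir_conn <- mir_edges |>
    group_by(id = .data$mirna_id) |>
    summarise(connectivity = dplyr::n_distinct(.data$cerna_id), .groups = "drop")
  type_map <- c(
    stats::setNames(pairs$type_a, pairs$rna_a),
    stats::setNames(pairs$type_b, pairs$rna_b)
  )
  nodes <- bind_rows(
    tibble(
      id = rna_ids,
      type = unname(type_map[rna_ids]) %||% NA_character_
    ) |>
      left_join(rna_conn, by = "id"),
    tibble(id = sort(unique(mir_edges$mirna_id)), type = "miRNA") |>
      left_join(mir_conn, by = "id")
  ) |>
    mutate(connectivity = dplyr::coalesce(.data$connectivity, 0L))
  structure(list(nodes = nodes, edges = net_edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tab <- table(x$nodes$type)
  cat(sprintf(
    "<cerna_network> %d nodes (%s); %d miRNA-ceRNA edges, %d ceRNA pairs\n",
    nrow(x$nodes),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    sum(x$edges$edge_type == "mirna-cerna"),
    sum(x$edges$edge_type == "cerna-cerna")
  ))
  invisible(x)
}

#' @rdname build_network
#' @param x a `cerna_network`.
#' @param type which table `tidy()` returns: `"edges"` or `"nodes"`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.cerna_network <- function(x, type = c("edges", "nodes"), ...) {
  switch(match.arg(type), edges = x$edges, nodes = x$nodes)
}

#' @rdname build_network
#' @exportS3Method generics::glance
glance.cerna_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_lncrna = sum(x$nodes$type == "lncRNA", na.rm = TRUE),
    n_mrna = sum(x$nodes$type == "mRNA", na.rm = TRUE),
    n_mirna = sum(x$nodes$type == "miRNA", na.rm = TRUE),
    n_mirna_edges = sum(x$edges$edge_type == "mirna-cerna"),
    n_pairs = sum(x$edges$edge_type == "cerna-cerna"),
    max_connectivity = if (nrow(x$nodes)) max(x$nodes$connectivity) else 0L
  )
}

#' Connectivity ranking and Sankey paths
#'
#' Ranks lncRNA and mRNA nodes by connectivity (descending; ties broken
#' lexicographically by id) and emits the lncRNA -> miRNA -> mRNA Sankey
#' triples for every retained two-edge path among the top-ranked nodes.
#'
#' @param network a [build_network()] result.
#' @param top_lnc,top_mrna how many top lncRNAs / mRNAs to keep
#'   (defaults 3 and 6).
#' @return A list: `lncrna` and `mrna` (ranked tibbles `id`,
#'   `connectivity`, `rank`) and `sankey` (tibble `lncrna_id`, `mirna_id`,
#'   `mrna_id`).
#' @export
connectivity_ranking <- function(network, top_lnc = 3, top_mrna = 6) {
  stopifnot(inherits(network, "cerna_network"))
  rank_type <- function(tp, top_n) {
    network$nodes |>
      filter(.data$type == tp) |>
      arrange(dplyr::desc(.data$connectivity), .data$id) |>
      mutate(rank = dplyr::row_number()) |>
      head(top_n) |>
      select("id", "connectivity", "rank")
  }
  top_l <- rank_type("lncRNA", top_lnc)
  top_m <- rank_type("mRNA", top_mrna)
  mir <- network$edges |> filter(.data$edge_type == "mirna-cerna")
  sankey <- mir |>
    filter(.data$to %in% top_l$id) |>
    select(lncrna_id = "to", mirna_id = "from") |>
    inner_join(
      mir |>
        filter(.data$to %in% top_m$id) |>
        select(mirna_id = "from", mrna_id = "to"),
      by = "mirna_id", relationship = "many-to-many"
    ) |>
    distinct() |>
    arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
  list(lncrna = top_l, mrna = top_m, sankey = sankey)
}

#' Serialize and restore a ceRNA network
#'
#' `write_network()` exports a network as tab-separated node/edge tables
#' (`format = "tsv"`, written to `<path>_edges.tsv` and `<path>_nodes.tsv`),
#' GraphML (`"graphml"`, via igraph) or JSON (`"json"`); `read_network()`
#' restores a network from the JSON or TSV form, giving a round trip equal
#' to the original object.
#'
#' @param network a `cerna_network`.
#' @param path output path (for `"tsv"`, a stem without extension).
#' @param format one of `"tsv"`, `"graphml"`, `"json"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `cerna_network`.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml", "json")) {
  stopifnot(inherits(network, "cerna_network"))
  format <- match.arg(format)
  switch(format,
    tsv = {
      readr::write_tsv(network$edges, paste0(path, "_edges.tsv"))
      readr::write_tsv(network$nodes, paste0(path, "_nodes.tsv"))
    },
    json = jsonlite::write_json(
      list(nodes = network$nodes, edges = network$edges),
      path,
      digits = NA, na = "null"
    ),
    graphml = {
      g <- igraph::graph_from_data_frame(
        d = as.data.frame(network$edges),
        vertices = as.data.frame(network$nodes),
        directed = FALSE
      )
      igraph::write_graph(g, path, format = "graphml")
    }
  )
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as_tibble(x$nodes)
    edges <- as_tibble(x$edges)
  } else {
    edges <- readr::read_tsv(paste0(path, "_edges.tsv"), show_col_types = FALSE)
    nodes <- readr::read_tsv(paste0(path, "_nodes.tsv"), show_col_types = FALSE)
  }
  if (nrow(nodes) == 0) {
    nodes <- tibble(id = character(), type = character(), connectivity = integer())
  }
  if (nrow(edges) == 0) {
    edges <- tibble(
      from = character(), to = character(), edge_type = character(),
      rho = numeric(), pearson_r = numeric(), hyper_p = numeric(),
      k = integer()
    )
  }
  nodes$connectivity <- as.integer(nodes$connectivity)
  edges$k <- as.integer(edges$k)
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}
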