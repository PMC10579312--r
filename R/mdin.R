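# Mass-difference network (MDiN) reconstruction over assigned formulas.
#
# Nodes are molecular formulas; an undirected edge links two formulas whose
# elemental difference equals one of a small catalogue of chemically
# meaningful transformations (methylation CH2, hydrogenation H2,
# oxygenation O, hydration H2O, decarboxylation-scale CO2, nitrogenations
# HCN/NH/NH3, sulfurizations S/SO/SO2/SO3/SO4). The catalogue deltas are
# elementally distinct, so at most one transformation can label a pair.

#' Default mass-difference transformation catalogue
#'
#' Thirteen transformations: CH2, H2, O, H2O, CO2, HCN, NH, NH3, S, SO,
#' SO2, SO3, SO4. The 12-entry variant without CO2 is available with
#' `include_co2 = FALSE`.
#'
#' @param include_co2 keep the CO2 entry (default `TRUE`)
#' @return data frame with columns `label` and `exact_mass`, plus element
#'   count columns giving each delta
#' @export
default_transformations <- function(include_co2 = TRUE) {
  labels <- c("CH2", "H2", "O", "H2O", "CO2", "HCN", "NH", "NH3",
              "S", "SO", "SO2", "SO3", "SO4")
  if (!include_co2) labels <- setdiff(labels, "CO2")
  transformation_catalogue(labels)
}

#' Build a transformation catalogue from formula-style delta strings
#'
#' @param labels character vector of elemental deltas (e.g. `"CH2"`); must
#'   be unique
#' @return data frame catalogue as in [default_transformations()]
#' @export
transformation_catalogue <- function(labels) {
  if (anyDuplicated(labels)) stop("transformation labels must be unique")
  m <- formula_matrix(labels)
  out <- data.frame(label = labels, exact_mass = monoisotopic_mass(m), m,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reconstruct the mass-difference network over a formula population
#'
#' For every pair of formulas whose elemental difference equals a catalogue
#' delta exactly, an undirected edge labeled with that transformation is
#' added ("removal or addition" collapse to one edge per pair).
#'
#' @param formulas character vector of formula strings or a formula matrix;
#'   must be free of duplicates
#' @param catalogue transformation catalogue
#'   (default [default_transformations()])
#' @return object of class `mdin`: list with `nodes` (formula strings),
#'   `edges` (data frame `from`, `to`, `transformation`),
#'   `per_transformation_counts`, `n_connected_nodes`
#' @export
build_network <- function(formulas, catalogue = default_transformations()) {
  m <- formula_matrix(formulas)
  keys <- formula_string(m)
  dup <- unique(keys[duplicated(keys)])
  if (length(dup) > 0) {
    stop("duplicate formulas in population: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  cat_m <- as.matrix(catalogue[, ELEMENT_ORDER, drop = FALSE])

  from <- character(0); to <- character(0); lab <- character(0)
  for (k in seq_len(nrow(cat_m))) {
    shifted <- sweep(m, 2, cat_m[k, ], "+")
    tgt <- formula_string(shifted)
    hit <- tgt %in% keys
    if (any(hit)) {
      from <- c(from, keys[hit])
      to <- c(to, tgt[hit])
      lab <- c(lab, rep(catalogue$label[k], sum(hit)))
    }
  }
  edges <- data.frame(from = from, to = to, transformation = lab,
                      stringsAsFactors = FALSE)
  new_mdin(keys, edges, catalogue)
}

new_mdin <- function(nodes, edges, catalogue) {
  counts <- table(factor(edges$transformation, levels = catalogue$label))
  connected <- unique(c(edges$from, edges$to))
  structure(list(nodes = nodes, edges = edges,
                 per_transformation_counts =
                   stats::setNames(as.integer(counts), names(counts)),
                 n_connected_nodes = length(connected),
                 catalogue = catalogue),
            class = "mdin")
}

#' @export
print.mdin <- function(x, ...) {
  cat(sprintf("Mass-difference network: %d nodes (%d connected), %d edges\n",
              length(x$nodes), x$n_connected_nodes, nrow(x$edges)))
  invisible(x)
}

#' Per-transformation percentages of an edge total
#'
#' @param counts named integer vector of per-transformation edge counts
#' @param n_edges total edge count (default `sum(counts)`)
#' @return named numeric vector of percentages (`count / n_edges * 100`);
#'   all zero when `n_edges` is 0
#' @export
transformation_percentages <- function(counts, n_edges = sum(counts)) {
  if (n_edges == 0) return(stats::setNames(rep(0, length(counts)), names(counts)))
  counts / n_edges * 100
}

#' Summary statistics of a mass-difference network
#'
#' @param net an `mdin`
#' @return list with `n_nodes`, `n_edges`, `n_connected_nodes`,
#'   `n_unconnected_nodes`, `counts`, `percentages` (per transformation,
#'   of all edges), and grouped percentages `pct_nitrogen` (HCN, NH, NH3)
#'   and `pct_sulfur` (S, SO, SO2, SO3, SO4)
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "mdin"))
  counts <- net$per_transformation_counts
  pct <- transformation_percentages(counts, nrow(net$edges))
  n_set <- intersect(c("HCN", "NH", "NH3"), names(counts))
  s_set <- intersect(c("S", "SO", "SO2", "SO3", "SO4"), names(counts))
  list(n_nodes = length(net$nodes),
       n_edges = nrow(net$edges),
       n_connected_nodes = net$n_connected_nodes,
       n_unconnected_nodes = length(net$nodes) - net$n_connected_nodes,
       counts = counts,
       percentages = pct,
       pct_nitrogen = sum(pct[n_set]),
       pct_sulfur = sum(pct[s_set]))
}

#' Mass-based network directly over peak m/z values
#'
#' Links two peaks when their m/z difference matches a catalogue exact mass
#' within `tol_ppm` (tolerance evaluated against the larger m/z). Enables
#' network reconstruction without formula assignment.
#'
#' @param pl a [peaklist]
#' @param catalogue transformation catalogue
#' @param tol_ppm difference tolerance in ppm
#' @return an `mdin` whose nodes are peak m/z values (formatted to 7
#'   decimals)
#' @export
mass_based_network <- function(pl, catalogue = default_transformations(),
                               tol_ppm = 1) {
  stopifnot(inherits(pl, "peaklist"), tol_ppm > 0)
  mz <- pl$mz
  keys <- sprintf("%.7f", mz)
  from <- character(0); to <- character(0); lab <- character(0)
  for (k in seq_len(nrow(catalogue))) {
    d <- catalogue$exact_mass[k]
    for (i in seq_along(mz)) {
      target <- mz[i] + d
      tol_da <- tol_ppm * 1e-6 * target
      j <- which(mz >= target - tol_da & mz <= target + tol_da)
      if (length(j) > 0) {
        from <- c(from, rep(keys[i], length(j)))
        to <- c(to, keys[j])
        lab <- c(lab, rep(catalogue$label[k], length(j)))
      }
    }
  }
  edges <- data.frame(from = from, to = to, transformation = lab,
                      stringsAsFactors = FALSE)
  new_mdin(keys, edges, catalogue)
}

#' Export a mass-difference network
#'
#' `edge_tsv` writes an edge table (`from`, `to`, `transformation`) plus a
#' companion `<path>.nodes.tsv` carrying every node (including unconnected
#' ones) with formula, family, H/C, O/C and mass attributes when the nodes
#' are parseable formulas. `graphml` writes a GraphML file through igraph
#' with the same attributes.
#'
#' @param net an `mdin`
#' @param path output path
#' @param format `"edge_tsv"` or `"graphml"`
#' @export
export_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  stopifnot(inherits(net, "mdin"))
  format <- match.arg(format)
  nodes <- node_attributes(net)
  if (format == "edge_tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

node_attributes <- function(net) {
  nodes <- data.frame(name = net$nodes, stringsAsFactors = FALSE)
  desc <- tryCatch(compute_descriptors(net$nodes), error = function(e) NULL)
  if (!is.null(desc)) {
    nodes$family <- desc$family
    nodes$hc_ratio <- desc$hc_ratio
    nodes$oc_ratio <- desc$oc_ratio
    nodes$mass <- desc$mass
  }
  nodes
}

#' Re-import a network exported as `edge_tsv`
#'
#' @param path path previously passed to [export_network()]
#' @param catalogue catalogue used when the network was built
#' @return an `mdin`
#' @export
import_network <- function(path, catalogue = default_transformations()) {
  edges <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, colClasses = "character")
  nodes_path <- paste0(path, ".nodes.tsv")
  nodes <- if (file.exists(nodes_path)) {
    utils::read.table(nodes_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)$name
  } else unique(c(edges$from, edges$to))
  new_mdin(nodes, edges, catalogue)
}
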