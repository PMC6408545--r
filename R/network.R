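# Non-redundant physical interactome, 1-step seed expansion and
# cross-disease network overlap.

# canonical unordered pair key
canonical_pairs <- function(a, b) {
  data.frame(a = pmin(a, b), b = pmax(a, b), stringsAsFactors = FALSE)
}

#' Build a non-redundant physical interactome
#'
#' Filters interaction records to physical interactions within one
#' organism, then collapses them to unique unordered symbol pairs: each
#' unique combination of interactors counts as a single interaction
#' regardless of direction, experimental system or publication.
#' Self-interactions are dropped (they never change 1-step reachability
#' and distort edge counts).
#'
#' @param records Interaction records (see [read_interactions()]).
#' @param taxon NCBI taxon id both interactors must carry (default 9606,
#'   human).
#' @return Object of class `interactome`: `list(edges, nodes, counts)`;
#'   `edges` is a data.frame of unordered pairs (`a` <= `b`
#'   lexicographically), `counts` reports `kept`, `dropped_genetic`,
#'   `dropped_organism`, `dropped_self` and `dropped_duplicate`.
#' @export
build_interactome <- function(records, taxon = 9606L) {
  n0 <- nrow(records)
  phys <- records$system_type == "physical"
  org <- records$organism_a == taxon & records$organism_b == taxon
  dropped_genetic <- sum(!phys)
  dropped_organism <- sum(phys & !org)
  rec <- records[phys & org, , drop = FALSE]
  self <- rec$symbol_a == rec$symbol_b
  dropped_self <- sum(self)
  rec <- rec[!self, , drop = FALSE]
  pairs <- canonical_pairs(rec$symbol_a, rec$symbol_b)
  dup <- duplicated(paste(pairs$a, pairs$b, sep = "\r"))
  dropped_duplicate <- sum(dup)
  edges <- pairs[!dup, , drop = FALSE]
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         nodes = sort(unique(c(edges$a, edges$b))),
         counts = list(input = n0, kept = nrow(edges),
                       dropped_genetic = dropped_genetic,
                       dropped_organism = dropped_organism,
                       dropped_self = dropped_self,
                       dropped_duplicate = dropped_duplicate)),
    class = "interactome"
  )
}

#' Convert an interactome back to interaction records
#'
#' Useful for round-trips and idempotence checks: every edge becomes one
#' physical, within-taxon record.
#'
#' @param inter An `interactome`.
#' @param taxon Taxon id to stamp on the records.
#' @return Data.frame of interaction records.
#' @export
as_interaction_records <- function(inter, taxon = 9606L) {
  data.frame(symbol_a = inter$edges$a, symbol_b = inter$edges$b,
             organism_a = taxon, organism_b = taxon,
             system_type = "physical", stringsAsFactors = FALSE)
}

#' Expand a seed gene list by direct 1-step interactions
#'
#' Extracts every interactome edge with at least one endpoint in the
#' seed set (the seeds' direct interactions, not the induced subgraph on
#' seeds plus neighbours). Seeds absent from the interactome are
#' reported separately as `unmapped` and excluded from the node set.
#'
#' @param inter An `interactome` from [build_interactome()].
#' @param seeds Character vector of seed gene symbols (non-empty).
#' @param label Provenance label for the network (e.g. `"AD"`, `"T2DM"`).
#' @return Object of class `disease_network`: `list(label, seeds, nodes,
#'   edges, unmapped)`.
#' @export
expand_seed_network <- function(inter, seeds, label = "other") {
  seeds <- unique(toupper(seeds))
  if (length(seeds) == 0) stop("seed list is empty", call. = FALSE)
  hit <- inter$edges$a %in% seeds | inter$edges$b %in% seeds
  edges <- inter$edges[hit, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$a, edges$b, intersect(seeds, inter$nodes))))
  structure(
    list(label = label, seeds = seeds, nodes = nodes, edges = edges,
         unmapped = setdiff(seeds, inter$nodes)),
    class = "disease_network"
  )
}

#' Overlap of two disease networks
#'
#' @param net_a,net_b `disease_network` objects.
#' @return List with `nodes` (shared symbols) and `edges` (shared
#'   unordered pairs, data.frame `a`, `b`).
#' @export
overlap_network <- function(net_a, net_b) {
  nodes <- intersect(net_a$nodes, net_b$nodes)
  key_a <- paste(net_a$edges$a, net_a$edges$b, sep = "\r")
  key_b <- paste(net_b$edges$a, net_b$edges$b, sep = "\r")
  edges <- net_a$edges[key_a %in% key_b, , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = sort(nodes), edges = edges)
}

#' Node table of a disease network
#'
#' @param net A `disease_network`.
#' @return Data.frame with columns `symbol`, `is_seed`, `degree`,
#'   `provenance`.
#' @export
network_node_table <- function(net) {
  deg <- table(c(net$edges$a, net$edges$b))
  data.frame(
    symbol = net$nodes,
    is_seed = net$nodes %in% net$seeds,
    degree = as.integer(deg[net$nodes]),
    provenance = net$label,
    stringsAsFactors = FALSE
  )
}
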