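#' Build a sociogram from an association matrix
#'
#' The sociogram is an undirected weighted graph whose nodes are the analysed
#' individuals and whose edges connect dyads with HWI strictly above the
#' threshold (default 0, i.e. an edge wherever two individuals were ever
#' identified in the same group). Node attributes carry the mark grade, tip
#' damage flag and number of sightings; edges carry the HWI as both `weight`
#' and `hwi`.
#'
#' @param m an `assoc_matrix` from [association_matrix()].
#' @param threshold HWI edge cutoff in `[0, 1)`; an edge requires
#'   `HWI > threshold`.
#' @param db the [sighting_database()] the matrix came from (for node
#'   attributes); optional.
#' @return an [igraph::igraph] object.
#' @export
build_sociogram <- function(m, threshold = 0, db = NULL) {
  stopifnot(inherits(m, "assoc_matrix"))
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop_domain("threshold must be in [0, 1)")
  adj <- m$hwi
  diag(adj) <- 0
  adj[adj <= threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$hwi <- igraph::E(g)$weight
  igraph::V(g)$n_sightings <- as.integer(m$n_sightings[igraph::V(g)$name])
  if (!is.null(db)) {
    idx <- match(igraph::V(g)$name, db$individuals$individual_id)
    igraph::V(g)$mark_grade <- db$individuals$mark_grade[idx]
    igraph::V(g)$tip_damage <- db$individuals$tip_damage[idx]
  }
  g
}

#' Partition a sociogram into communities
#'
#' Communities are the connected components of the association graph: sets of
#' individuals linked, directly or through intermediates, by shared group
#' membership. Components are labelled `A`, `B`, `C`, ... in order of
#' decreasing size, ties broken by the lexicographically smallest member id,
#' so the labelling is fully deterministic and the largest cluster is always
#' `A`. Every node receives a label with provenance `PRIMARY` (it was part of
#' the network analysis).
#'
#' @param g a sociogram from [build_sociogram()].
#' @return An object of class `community_partition`: a data.frame with
#'   columns `individual_id`, `label`, `provenance`, and attribute `labels`
#'   giving the ordered label vector.
#' @export
detect_communities <- function(g) {
  stopifnot(inherits(g, "igraph"))
  if (igraph::vcount(g) < 1)
    stop_domain("sociogram has no nodes")
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  members <- split(ids, comp$membership)
  first_member <- vapply(members, function(x) min(x), character(1))
  ord <- order(-lengths(members), first_member)
  members <- members[ord]
  labels <- community_labels(length(members))

  out <- data.frame(
    individual_id = unlist(members, use.names = FALSE),
    label = rep(labels, lengths(members)),
    provenance = "PRIMARY")
  out <- out[order(out$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, labels = labels, class = c("community_partition",
                                            "data.frame"))
}

#' @export
print.community_partition <- function(x, ...) {
  tab <- table(factor(x$label, levels = c(attr(x, "labels"), "UNASSIGNED")))
  tab <- tab[tab > 0]
  cat("<community_partition>", nrow(x), "individuals in", length(tab),
      "group(s):", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Assign less-marked individuals to communities via their associates
#'
#' Permanently marked individuals define the network; temporarily and
#' superficially marked individuals are then assigned by a secondary rule:
#' collect the community labels of every permanently marked individual the
#' animal was ever identified with (co-occurrence in any encounter), and
#' assign the animal to that community if all such associates belong to a
#' single one. Individuals with no permanently marked associates, or with
#' associates in more than one community, stay `UNASSIGNED` — an explicit
#' outcome that downstream summaries count rather than drop.
#'
#' @param db a [sighting_database()].
#' @param partition a `community_partition` over all permanently marked
#'   individuals of `db` (from [detect_communities()]).
#' @return The extended `community_partition`: `PRIMARY` rows unchanged, one
#'   `SECONDARY` row added per non-permanent individual (label or
#'   `"UNASSIGNED"`).
#' @export
assign_unmarked <- function(db, partition) {
  stopifnot(inherits(db, "sighting_db"),
            inherits(partition, "community_partition"))
  perm_ids <- db$individuals$individual_id[
    db$individuals$mark_grade == "PERMANENT"]
  missing <- setdiff(perm_ids, partition$individual_id)
  if (length(missing))
    stop_domain("partition does not cover all permanently marked ",
                "individuals: ", paste(utils::head(missing, 5),
                                       collapse = ", "))
  label_of <- setNames(partition$label, partition$individual_id)

  other_ids <- setdiff(db$individuals$individual_id, perm_ids)
  enc_members <- split(db$sightings$individual_id, db$sightings$encounter_id)
  encs_of <- split(db$sightings$encounter_id, db$sightings$individual_id)

  sec <- vapply(other_ids, function(id) {
    assoc <- unique(unlist(enc_members[encs_of[[id]]], use.names = FALSE))
    assoc_labels <- unique(label_of[intersect(assoc, perm_ids)])
    if (length(assoc_labels) == 1) assoc_labels else "UNASSIGNED"
  }, character(1))

  out <- rbind(
    as.data.frame(partition),
    data.frame(individual_id = other_ids, label = unname(sec),
               provenance = "SECONDARY"))
  out <- out[order(out$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, labels = attr(partition, "labels"),
            class = c("community_partition", "data.frame"))
}

#' Export a sociogram to GraphML
#'
#' Writes the graph with node attributes (`community` when a partition is
#' supplied, `mark_grade`, `tip_damage`, `n_sightings`) and the `hwi` edge
#' attribute, readable by standard network tools.
#'
#' @param g a sociogram.
#' @param path output file path (`.graphml`).
#' @param partition optional `community_partition` used to attach a
#'   `community` node attribute.
#' @return `path`, invisibly.
#' @export
write_sociogram <- function(g, path, partition = NULL) {
  stopifnot(inherits(g, "igraph"))
  if (!is.null(partition)) {
    lab <- setNames(partition$label, partition$individual_id)
    igraph::V(g)$community <- unname(lab[igraph::V(g)$name])
  }
  if (!is.null(igraph::V(g)$tip_damage))
    igraph::V(g)$tip_damage <- as.integer(igraph::V(g)$tip_damage)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a sociogram edge list to CSV
#'
#' @param g a sociogram.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "igraph"))
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[names(el) == "from"] <- "id_a"
  names(el)[names(el) == "to"] <- "id_b"
  el$weight <- NULL
  write.csv(el, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a community partition to CSV
#'
#' @param partition a `community_partition`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "community_partition"))
  write.csv(as.data.frame(partition), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
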