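# Knowledge-graph assembly. Node types (12): Resource, HPO, UMLS,
# EricTerm, AIRS, ChallengingBehavior, Topic, Unigram, Province, City,
# Age, Category. Relations (9): hasParent, isLocatedIn, inProvince,
# CONTAINS, IS_ASSOCIATED_WITH, OCCURRED_TOGETHER, belongsToTopic,
# describedBy, containsNgram. Weight provenance: CONTAINS carries the
# pivoted-normalization entity relevance (or the classifier probability on
# Resource->Category edges), isLocatedIn the location proportion,
# OCCURRED_TOGETHER the document co-occurrence count, IS_ASSOCIATED_WITH
# the number of resources where the shared canonical term is detected
# under both vocabularies, belongsToTopic theta, describedBy phi, and
# containsNgram the theta-phi product. inProvince and hasParent are
# unweighted.

.node_types <- c("Resource", "HPO", "UMLS", "EricTerm", "AIRS",
                 "ChallengingBehavior", "Topic", "Unigram", "Province",
                 "City", "Age", "Category")

.relations <- c("hasParent", "isLocatedIn", "inProvince", "CONTAINS",
                "IS_ASSOCIATED_WITH", "OCCURRED_TOGETHER", "belongsToTopic",
                "describedBy", "containsNgram")

.weighted_relations <- c("CONTAINS", "isLocatedIn", "IS_ASSOCIATED_WITH",
                         "OCCURRED_TOGETHER", "belongsToTopic",
                         "describedBy", "containsNgram")

.vocab_node_type <- c(HPO = "HPO", UMLS = "UMLS", ERIC = "EricTerm",
                      AIRS = "AIRS", BEHAVIOR = "ChallengingBehavior",
                      AGE = "Age")

.entity_node_types <- unname(.vocab_node_type)

node_id_resource <- function(doc_id) sprintf("res:%s", doc_id)
node_id_entity <- function(vocab, canonical) sprintf("ent:%s:%s", vocab, canonical)
node_id_topic <- function(label) sprintf("topic:%s", label)
node_id_unigram <- function(word) sprintf("uni:%s", word)
node_id_city <- function(city) sprintf("city:%s", city)
node_id_province <- function(prov) sprintf("prov:%s", prov)
node_id_category <- function(cat) sprintf("cat:%s", cat)

.empty_nodes <- function() {
  data.frame(node_id = character(), node_type = character(),
             canonical = character(), concept_id = character(),
             url = character(), source = character(),
             resource_type = character(), subtype = character(),
             label = character(), stringsAsFactors = FALSE)
}

.node_row <- function(node_id, node_type, canonical = NA, concept_id = NA,
                      url = NA, source = NA, resource_type = NA,
                      subtype = NA, label = NA) {
  data.frame(node_id = node_id, node_type = node_type,
             canonical = as.character(canonical),
             concept_id = as.character(concept_id), url = as.character(url),
             source = as.character(source),
             resource_type = as.character(resource_type),
             subtype = as.character(subtype), label = as.character(label),
             stringsAsFactors = FALSE)
}

.edge_rows <- function(src, rel, dst, weight = NA_real_) {
  if (!length(src)) {
    return(data.frame(src = character(), rel = character(),
                      dst = character(), weight = numeric()))
  }
  data.frame(src = src, rel = rel, dst = dst, weight = as.numeric(weight),
             stringsAsFactors = FALSE)
}

#' Build the weighted knowledge graph
#'
#' Assembles all upstream annotations computed on one corpus into a typed,
#' weighted property graph: one Resource node per document; CONTAINS edges
#' to vocabulary, challenging-behavior and age nodes weighted by entity
#' relevance; Resource->Category membership edges weighted by classifier
#' probability; belongsToTopic / describedBy / containsNgram edges from
#' the leaf topic models (sparsified at `floor`); isLocatedIn proportion
#' edges plus unweighted inProvince and hasParent; IS_ASSOCIATED_WITH
#' between vocabularies sharing a canonical term; OCCURRED_TOGETHER with
#' document co-occurrence counts.
#'
#' @param corpus `ndkg_corpus` data frame.
#' @param relevance data frame from [relevance_scores()] (behavior mentions
#'   collapsed to categories, see [collapse_behavior()]).
#' @param cooccur data frame from [cooccurrences()] on the same mentions.
#' @param leaves list from [leaf_topics()], or NULL to skip topic edges.
#' @param hierarchy the full `ndkg_htm_node` (used for containsNgram
#'   products); may be NULL when `leaves` is NULL.
#' @param categories data frame `doc_id`, `category`, `prob` (classifier
#'   memberships), or NULL.
#' @param locations named list (by doc_id) of `ndkg_locweights`, or NULL.
#' @param params list of run parameters recorded in the manifest (pivot,
#'   slope, log_base, floor, seeds, thresholds...). `floor` defaults to
#'   1e-3 and sparsifies the three topic weight families.
#' @param lexicon optional lexicon data frame used to attach concept ids
#'   to vocabulary nodes.
#' @return object of class `ndkg_graph`: `nodes`, `edges`, `manifest`.
#' @export
build_graph <- function(corpus, relevance, cooccur = NULL, leaves = NULL,
                        hierarchy = NULL, categories = NULL, locations = NULL,
                        params = list(), lexicon = NULL) {
  floor_w <- params$floor %||% 1e-3
  nodes <- list()
  edges <- list()

  nodes$resources <- .node_row(node_id_resource(corpus$doc_id), "Resource",
                               url = corpus$url, source = corpus$source,
                               resource_type = corpus$resource_type)

  # hasParent (unweighted), only for parents present in the corpus
  hp <- corpus[!is.na(corpus$parent_id) & corpus$parent_id %in% corpus$doc_id, ]
  edges$hasParent <- .edge_rows(node_id_resource(hp$doc_id), "hasParent",
                                node_id_resource(hp$parent_id))

  # entity nodes + CONTAINS with relevance weights
  if (!is.null(relevance) && nrow(relevance)) {
    ent <- unique(relevance[c("canonical", "vocab")])
    ntype <- .vocab_node_type[ent$vocab]
    if (anyNA(ntype)) {
      stop_ndkg("relevance table contains non-entity vocab: ",
                paste(unique(ent$vocab[is.na(ntype)]), collapse = ", "))
    }
    cid <- rep(NA_character_, nrow(ent))
    if (!is.null(lexicon)) {
      lx <- validate_lexicon(lexicon)
      m <- match(paste(ent$vocab, ent$canonical),
                 paste(lx$vocab, lx$canonical))
      cid <- lx$concept_id[m]
    }
    nodes$entities <- .node_row(
      node_id_entity(ent$vocab, ent$canonical), unname(ntype),
      canonical = ent$canonical, concept_id = cid,
      subtype = ifelse(ntype == "Age", ent$canonical, NA)
    )
    edges$contains <- .edge_rows(
      node_id_resource(relevance$doc_id), "CONTAINS",
      node_id_entity(relevance$vocab, relevance$canonical),
      relevance$weight
    )
    # IS_ASSOCIATED_WITH: same canonical term under different vocabularies;
    # weight = number of documents where both are detected (0 if never).
    assoc <- list()
    for (cn in unique(ent$canonical[duplicated(ent$canonical)])) {
      vs <- sort(ent$vocab[ent$canonical == cn])
      cmb <- utils::combn(vs, 2)
      for (j in seq_len(ncol(cmb))) {
        v1 <- cmb[1, j]; v2 <- cmb[2, j]
        d1 <- relevance$doc_id[relevance$canonical == cn & relevance$vocab == v1]
        d2 <- relevance$doc_id[relevance$canonical == cn & relevance$vocab == v2]
        assoc[[length(assoc) + 1L]] <- .edge_rows(
          node_id_entity(v1, cn), "IS_ASSOCIATED_WITH",
          node_id_entity(v2, cn), length(intersect(d1, d2)))
      }
    }
    if (length(assoc)) edges$assoc <- do.call(rbind, assoc)
  }

  # OCCURRED_TOGETHER with document co-occurrence counts
  if (!is.null(cooccur) && nrow(cooccur)) {
    pa <- strsplit(cooccur$a, ":", fixed = TRUE)
    pb <- strsplit(cooccur$b, ":", fixed = TRUE)
    key_to_id <- function(p) node_id_entity(p[[1]], paste(p[-1], collapse = ":"))
    edges$occ <- .edge_rows(
      vapply(pa, key_to_id, character(1)), "OCCURRED_TOGETHER",
      vapply(pb, key_to_id, character(1)), cooccur$count)
  }

  # topic, unigram and the three LDA weight families
  if (!is.null(leaves) && length(leaves)) {
    nodes$topics <- .node_row(
      node_id_topic(vapply(leaves, `[[`, character(1), "label")), "Topic",
      label = vapply(leaves, `[[`, character(1), "label"))
    uni_words <- character()
    bt <- list(); db <- list(); cn <- list()
    for (lf in leaves) {
      keep <- lf$theta >= floor_w
      if (any(keep)) {
        bt[[length(bt) + 1L]] <- .edge_rows(
          node_id_resource(names(lf$theta)[keep]), "belongsToTopic",
          node_id_topic(lf$label), unname(lf$theta[keep]))
      }
      pk <- lf$phi >= floor_w
      if (any(pk)) {
        db[[length(db) + 1L]] <- .edge_rows(
          node_id_topic(lf$label), "describedBy",
          node_id_unigram(names(lf$phi)[pk]), unname(lf$phi[pk]))
        uni_words <- c(uni_words, names(lf$phi)[pk])
      }
    }
    if (!is.null(hierarchy)) {
      for (node in htm_nodes(hierarchy)) {
        leaf_docs <- node$doc_ids[node$is_leaf_topic[node$assign]]
        if (!length(leaf_docs)) next
        th <- node$model$theta[match(leaf_docs, node$doc_ids), , drop = FALSE]
        prod <- contains_ngram_weights(th, node$model$phi)
        idx <- which(prod >= floor_w, arr.ind = TRUE)
        if (nrow(idx)) {
          cn[[length(cn) + 1L]] <- .edge_rows(
            node_id_resource(leaf_docs[idx[, 1]]), "containsNgram",
            node_id_unigram(colnames(node$model$phi)[idx[, 2]]),
            prod[idx])
          uni_words <- c(uni_words, colnames(node$model$phi)[idx[, 2]])
        }
      }
    }
    uni_words <- unique(uni_words)
    if (length(uni_words)) {
      nodes$unigrams <- .node_row(node_id_unigram(uni_words), "Unigram",
                                  label = uni_words)
    }
    if (length(bt)) edges$belongs <- do.call(rbind, bt)
    if (length(db)) edges$described <- do.call(rbind, db)
    if (length(cn)) edges$ngram <- do.call(rbind, cn)
  }

  # classifier memberships
  if (!is.null(categories) && nrow(categories)) {
    nodes$categories <- .node_row(
      node_id_category(unique(categories$category)), "Category",
      subtype = unique(categories$category))
    edges$cat <- .edge_rows(node_id_resource(categories$doc_id), "CONTAINS",
                            node_id_category(categories$category),
                            categories$prob)
  }

  # locations
  if (!is.null(locations) && length(locations)) {
    cities <- character(); provs <- character(); cp <- character()
    loc_edges <- list()
    for (doc in names(locations)) {
      lw <- locations[[doc]]
      if (length(lw$city)) {
        loc_edges[[length(loc_edges) + 1L]] <- .edge_rows(
          node_id_resource(doc), "isLocatedIn",
          node_id_city(names(lw$city)), unname(lw$city))
        cities <- c(cities, names(lw$city))
      }
      if (length(lw$province)) {
        loc_edges[[length(loc_edges) + 1L]] <- .edge_rows(
          node_id_resource(doc), "isLocatedIn",
          node_id_province(names(lw$province)), unname(lw$province))
        provs <- c(provs, names(lw$province))
      }
      cp <- c(cp, stats::setNames(unname(lw$city_province), names(lw$city_province)))
    }
    cities <- unique(cities); provs <- unique(provs)
    cp <- cp[!duplicated(names(cp))]
    provs <- unique(c(provs, unname(cp)))
    if (length(cities)) nodes$cities <- .node_row(node_id_city(cities), "City", label = cities)
    if (length(provs)) nodes$provinces <- .node_row(node_id_province(provs), "Province", label = provs)
    if (length(loc_edges)) edges$located <- do.call(rbind, loc_edges)
    if (length(cp)) {
      edges$inprov <- .edge_rows(node_id_city(names(cp)), "inProvince",
                                 node_id_province(unname(cp)))
    }
  }

  nodes_df <- do.call(rbind, c(list(.empty_nodes()), unname(nodes)))
  nodes_df <- nodes_df[!duplicated(nodes_df$node_id), , drop = FALSE]
  rownames(nodes_df) <- NULL
  edges_df <- do.call(rbind, c(list(.edge_rows(character())), unname(edges)))
  rownames(edges_df) <- NULL

  dangling <- setdiff(c(edges_df$src, edges_df$dst), nodes_df$node_id)
  if (length(dangling)) {
    bad <- edges_df[edges_df$src %in% dangling | edges_df$dst %in% dangling, ][1, ]
    stop_ndkg("edge references absent node: ", bad$src, " -[", bad$rel, "]-> ", bad$dst)
  }

  manifest <- c(params, list(
    floor = floor_w,
    n_nodes = nrow(nodes_df), n_edges = nrow(edges_df),
    built = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ))
  structure(list(nodes = nodes_df, edges = edges_df, manifest = manifest),
            class = "ndkg_graph")
}

#' @export
print.ndkg_graph <- function(x, ...) {
  cat("<ndkg_graph>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  tn <- table(x$nodes$node_type)
  cat("  nodes:", paste(names(tn), tn, sep = "=", collapse = " "), "\n")
  te <- table(x$edges$rel)
  cat("  edges:", paste(names(te), te, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# endpoint legality: relation -> list of allowed (src, dst) type pairs
.schema_rules <- function() {
  ent <- .entity_node_types
  list(
    hasParent = list(src = "Resource", dst = "Resource"),
    isLocatedIn = list(src = "Resource", dst = c("City", "Province")),
    inProvince = list(src = "City", dst = "Province"),
    CONTAINS = list(src = "Resource", dst = c(ent, "Category")),
    IS_ASSOCIATED_WITH = list(src = ent, dst = ent),
    OCCURRED_TOGETHER = list(src = ent, dst = ent),
    belongsToTopic = list(src = "Resource", dst = "Topic"),
    describedBy = list(src = "Topic", dst = "Unigram"),
    containsNgram = list(src = "Resource", dst = "Unigram")
  )
}

#' Validate a knowledge graph against the schema
#'
#' Checks that every edge endpoint exists and has a legal type for its
#' relation, and that weights are present exactly on the weighted
#' relations (CONTAINS, isLocatedIn, IS_ASSOCIATED_WITH,
#' OCCURRED_TOGETHER, belongsToTopic, describedBy, containsNgram) and
#' absent on inProvince and hasParent.
#'
#' @param kg an `ndkg_graph`.
#' @return character vector of violations; empty means the graph conforms.
#' @export
validate_schema <- function(kg) {
  v <- character()
  nd <- kg$nodes; ed <- kg$edges
  if (anyDuplicated(nd$node_id)) v <- c(v, "duplicate node ids")
  bad_type <- !nd$node_type %in% .node_types
  if (any(bad_type)) {
    v <- c(v, paste("unknown node type:", unique(nd$node_type[bad_type])))
  }
  bad_rel <- !ed$rel %in% .relations
  if (any(bad_rel)) v <- c(v, paste("unknown relation:", unique(ed$rel[bad_rel])))
  type_of <- stats::setNames(nd$node_type, nd$node_id)
  rules <- .schema_rules()
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    st <- unname(type_of[e$src])
    dt <- unname(type_of[e$dst])
    if (is.na(st) || is.na(dt)) {
      v <- c(v, sprintf("dangling edge %s -[%s]-> %s", e$src, e$rel, e$dst))
      next
    }
    rule <- rules[[e$rel]]
    if (!is.null(rule) &&
        (!st %in% rule$src || !dt %in% rule$dst)) {
      v <- c(v, sprintf("illegal endpoints for %s: %s -> %s", e$rel, st, dt))
    }
    weighted <- e$rel %in% .weighted_relations
    if (weighted && is.na(e$weight)) {
      v <- c(v, sprintf("missing weight on %s edge %s -> %s", e$rel, e$src, e$dst))
    }
    if (!weighted && !is.na(e$weight)) {
      v <- c(v, sprintf("unexpected weight on %s edge %s -> %s", e$rel, e$src, e$dst))
    }
  }
  v
}
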