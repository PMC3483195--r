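# Forward simulator of protein family and domain evolution along a species
# tree. Families arise on branches (founding a new domain de novo or
# shuffling domains of existing families), die as whole characters, and
# their members duplicate and delete as a per-lineage birth-death process;
# every event is logged per branch as ground truth. Sequences are never
# simulated: pairwise distances are path lengths on the true gene trees
# (plus optional Gaussian noise), which downstream tree building inverts
# exactly at zero noise.

#' Simulation parameter set
#'
#' Defaults are the package's documented study conditions at desk scale
#' (a few hundred families over the 11-taxon fixture tree). Rates are per
#' unit branch length (substitutions/site).
#'
#' @param root_families Families present in the root genome.
#' @param founding_extra_mean Mean of the geometric number of founding
#'   members beyond 2 (every family starts with >= 2 members — a single
#'   sequence is not a family).
#' @param domain_pool Distinct domains in the root genome.
#' @param fam_birth_rate Family births per existing family per unit length.
#' @param denovo_fraction Fraction of family births founding one new domain;
#'   the rest shuffle >= 2 domains drawn from distinct existing families.
#' @param fam_death_rate Family deaths per family per unit length.
#' @param dup_rate Member duplications per gene lineage per unit length.
#' @param del_rate Member deletions per gene lineage per unit length.
#' @param dom_birth_rate Standalone new-domain births per unit length
#'   (each appended to one existing family from that branch on).
#' @param death_mode `"constrained"` keeps every death recoverable by Dollo
#'   parsimony (the surviving leaf set keeps its LCA, no two empty sister
#'   subtrees, and no death directly below a branch carrying a true
#'   duplication); `"free"` places deaths anywhere the family is alive,
#'   which can make Dollo undercount - useful for demonstrating the bias.
#' @param edge_drop Probability a true within-family similarity edge is
#'   dropped.
#' @param edge_false Expected false between-family edges as a fraction of
#'   the true edge count.
#' @param dist_noise_sd Gaussian noise s.d. added to true gene-tree
#'   distances.
#' @param founding_eps Branch length separating founding members' join
#'   nodes (must be > 0 so the topology is identifiable).
#' @return Named list of parameters.
#' @export
simParams <- function(root_families = 60L, founding_extra_mean = 1,
                      domain_pool = 40L, fam_birth_rate = 0.4,
                      denovo_fraction = 0.3, fam_death_rate = 0.1,
                      dup_rate = 0.3, del_rate = 0.2, dom_birth_rate = 0.05,
                      death_mode = c("constrained", "free"),
                      edge_drop = 0.02, edge_false = 0.005,
                      dist_noise_sd = 0.05, founding_eps = 0.02) {
  stopifnot(root_families >= 1, fam_birth_rate >= 0, fam_death_rate >= 0,
            dup_rate >= 0, del_rate >= 0, dom_birth_rate >= 0,
            denovo_fraction >= 0, denovo_fraction <= 1,
            edge_drop >= 0, edge_drop <= 1, edge_false >= 0,
            dist_noise_sd >= 0, founding_eps > 0)
  list(root_families = as.integer(root_families),
       founding_extra_mean = founding_extra_mean,
       domain_pool = as.integer(domain_pool),
       fam_birth_rate = fam_birth_rate, denovo_fraction = denovo_fraction,
       fam_death_rate = fam_death_rate, dup_rate = dup_rate,
       del_rate = del_rate, dom_birth_rate = dom_birth_rate,
       death_mode = match.arg(death_mode), edge_drop = edge_drop,
       edge_false = edge_false, dist_noise_sd = dist_noise_sd,
       founding_eps = founding_eps)
}

# Mutable gene-tree store for one family: parent/length/label per node.
newGeneStore <- function() {
  e <- new.env(parent = emptyenv())
  e$parent <- integer(0); e$plen <- numeric(0); e$label <- character(0)
  e
}
gsAdd <- function(gs, parent, plen, label = NA_character_) {
  id <- length(gs$parent) + 1L
  gs$parent[id] <- parent; gs$plen[id] <- plen; gs$label[id] <- label
  id
}

# Prune extinct lineages and suppress unary nodes; return newick (or NULL
# if fewer than 2 leaves survive). Parents always have smaller ids than
# their children, so a single reverse sweep accumulates leaf counts.
gsNewick <- function(gs) {
  n <- length(gs$parent)
  if (n == 0L) return(NULL)
  kids <- vector("list", n)
  for (i in seq_len(n)) if (gs$parent[i] > 0)
    kids[[gs$parent[i]]] <- c(kids[[gs$parent[i]]], i)
  nleaf <- ifelse(is.na(gs$label), 0L, 1L)
  for (i in seq(n, 1L)) if (gs$parent[i] > 0)
    nleaf[gs$parent[i]] <- nleaf[gs$parent[i]] + nleaf[i]
  roots <- which(gs$parent == 0L)
  if (length(roots) != 1L || nleaf[roots] < 2L) return(NULL)
  build <- function(v, extra) {
    repeat {
      if (!is.na(gs$label[v]))
        return(sprintf("%s:%.9f", gs$label[v], gs$plen[v] + extra))
      ks <- kids[[v]]
      ks <- ks[nleaf[ks] > 0]
      if (length(ks) >= 2L)
        return(sprintf("(%s):%.9f",
                       paste(vapply(ks, function(k) build(k, 0), ""),
                             collapse = ","), gs$plen[v] + extra))
      extra <- extra + gs$plen[v]   # unary node vanishes into its child edge
      v <- ks[1]
    }
  }
  s <- build(roots, 0)
  paste0(sub(":[0-9.]+$", "", s), ";")
}

#' Forward-simulate family and domain evolution
#'
#' @param params Parameter list from [simParams()].
#' @param tree Rooted binary species `phylo` tree with branch lengths
#'   (default: the packaged 11-taxon fixture).
#' @param seed Mandatory RNG seed; identical seeds give identical output.
#' @return List with `dataset` (proteins, similarity edges, domain hits,
#'   per-family distance matrices and gene-tree newicks, annotation slots,
#'   species tree) and `truth` (per-branch event counts, per-family birth
#'   and death branches, presence matrix, domain origins).
#' @export
simulateFamDom <- function(params = simParams(), tree = speciesTreeFixture(),
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  nn <- ntip + tree$Nnode
  par <- nodeParents(tree)
  kids <- nodeChildren(tree)
  tu <- tipsUnder(tree)
  len <- numeric(nn)
  len[tree$edge[, 2]] <- tree$edge.length
  preord <- setdiff(unique(c(root, tree$edge[rev(ape::postorder(tree)), 2])), 0L)
  preord <- preord[preord != root]

  fams <- list()          # per family: birth_node, deaths, n0, domains, dom_attach
  gstores <- list()
  open <- vector("list", nn)      # open[[node]][[fam]] = list of c(attach, acc)
  for (v in seq_len(nn)) open[[v]] <- list()
  ev <- matrix(0L, nn, 5, dimnames = list(NULL,
          c("fam_birth", "fam_death", "dup", "del", "dom_birth")))
  prot_counter <- 0L
  proteins <- list()      # per family: data.frame(protein, species)
  dom_counter <- 0L
  dom_origin <- character(0)      # creation node per domain, named by domain
  newDomain <- function(node) {
    dom_counter <<- dom_counter + 1L
    d <- sprintf("PFS%04d", dom_counter)
    dom_origin[d] <<- as.character(node)
    ev[node, "dom_birth"] <<- ev[node, "dom_birth"] + 1L
    d
  }

  evolveSegment <- function(fid, attach, acc, pos, v) {
    gs <- gstores[[fid]]
    rate <- params$dup_rate + params$del_rate
    repeat {
      w <- if (rate > 0) rexp(1, rate) else Inf
      if (pos + w >= len[v] || v == root) {
        # reached the bottom of the branch (the root "branch" has length 0)
        plen <- acc + (if (v == root) 0 else len[v] - pos)
        if (v <= ntip) {
          prot_counter <<- prot_counter + 1L
          lab <- sprintf("%s_g%05d", tree$tip.label[v], prot_counter)
          gsAdd(gs, attach, plen, lab)
          proteins[[fid]] <<- rbind(proteins[[fid]],
            data.frame(protein = lab, species = tree$tip.label[v],
                       stringsAsFactors = FALSE))
        } else {
          # speciation: materialize the node so the segment above it is
          # shared by both child branches exactly once
          s <- gsAdd(gs, attach, plen)
          open[[v]][[fid]] <<- c(open[[v]][[fid]], list(c(s, 0)))
        }
        return(invisible(NULL))
      }
      pos <- pos + w
      if (runif(1) < params$dup_rate / rate) {
        ev[v, "dup"] <<- ev[v, "dup"] + 1L
        node <- gsAdd(gs, attach, acc + w)
        evolveSegment(fid, node, 0, pos, v)    # one branch recurses,
        attach <- node; acc <- 0               # the other continues here
      } else {
        ev[v, "del"] <<- ev[v, "del"] + 1L
        return(invisible(NULL))
      }
    }
  }

  foundFamily <- function(node, pos, alive_ids) {
    fid <- sprintf("T%04d", length(fams) + 1L)
    n0 <- 2L + rgeom(1, 1 / (1 + params$founding_extra_mean))
    # domain architecture: de novo or shuffled from existing families
    donors <- alive_ids[vapply(alive_ids, function(a)
      length(fams[[a]]$domains) > 0, TRUE)]
    if (length(donors) >= 2L && runif(1) >= params$denovo_fraction) {
      pick <- sample(donors, sample(2:min(3, length(donors)), 1))
      doms <- vapply(pick, function(a) {
        ds <- fams[[a]]$domains
        ds[sample.int(length(ds), 1)]
      }, character(1))
      shuffled <- TRUE
    } else {
      doms <- newDomain(node)
      shuffled <- FALSE
    }
    fams[[fid]] <<- list(id = fid, birth_node = node, deaths = integer(0),
                         n0 = n0, domains = unname(doms),
                         dom_attach = setNames(rep(node, length(doms)), NULL),
                         shuffled = shuffled)
    gstores[[fid]] <<- newGeneStore()
    proteins[[fid]] <<- data.frame(protein = character(0),
                                   species = character(0),
                                   stringsAsFactors = FALSE)
    ev[node, "fam_birth"] <<- ev[node, "fam_birth"] + 1L
    if (n0 > 1L) ev[node, "dup"] <<- ev[node, "dup"] + (n0 - 1L)
    gs <- gstores[[fid]]
    topid <- gsAdd(gs, 0L, 0)
    cur <- topid
    lineage_attach <- integer(0)
    for (i in seq_len(n0 - 1L)) {
      lineage_attach <- c(lineage_attach, cur)
      if (i < n0 - 1L) cur <- gsAdd(gs, cur, params$founding_eps)
    }
    lineage_attach <- c(lineage_attach, cur)   # two lineages on the last join
    if (n0 == 2L) lineage_attach <- c(topid, topid)
    for (a in lineage_attach)
      evolveSegment(fid, a, params$founding_eps, pos, node)
    fid
  }

  # family alive (has open lineages) at node v
  aliveAt <- function(v) names(open[[v]])[vapply(open[[v]], length, 0L) > 0]

  # would killing family f on branch into v still be exactly recoverable?
  deathAllowed <- function(fid, v) {
    f <- fams[[fid]]
    if (params$death_mode == "free") {
      # only require that some leaf keeps the family
      leaves_left <- presentTips(f, c(f$deaths, v))
      return(length(leaves_left) > 0)
    }
    p <- par[v]
    sib <- setdiff(kids[[p]], v)
    # no duplication directly above: a dup on the edge into par(v) would be
    # remapped below par(v) once v's subtree is empty
    if (p != f$birth_node || TRUE) {
      if (ev[p, "dup"] > 0 && familyDupOnBranch(fid, p)) return(FALSE)
    }
    leaves_left <- presentTips(f, c(f$deaths, v))
    if (length(leaves_left) == 0) return(FALSE)
    # LCA of survivors must stay at the birth node
    if (f$birth_node <= ntip) return(FALSE)    # single-tip clade: death kills all
    lca_now <- treeLca(tree, leaves_left)
    if (lca_now != f$birth_node && f$birth_node != root) return(FALSE)
    if (f$birth_node == root && lca_now != root) return(FALSE)
    # no node may end with both child subtrees empty: sister must keep leaves
    for (d in c(f$deaths, v)) {
      s <- setdiff(kids[[par[d]]], d)
      if (length(s) && !any(tu[[s]] %in% leaves_left)) return(FALSE)
    }
    TRUE
  }

  famDupBranches <- new.env(parent = emptyenv())  # fid -> nodes with true dups
  familyDupOnBranch <- function(fid, node) {
    b <- famDupBranches[[fid]]
    !is.null(b) && node %in% b
  }
  noteDups <- function(fid, node, before, after) {
    if (after > before) {
      famDupBranches[[fid]] <- c(famDupBranches[[fid]], node)
    }
  }

  presentTips <- function(f, deaths) {
    base <- if (f$birth_node == root) tree$tip.label else tu[[f$birth_node]]
    dead <- unique(unlist(tu[deaths]))
    setdiff(base, dead)
  }

  # ---- root genome ----
  pool <- replicate(params$domain_pool, newDomain(root))
  for (i in seq_len(params$root_families)) {
    fid <- sprintf("T%04d", length(fams) + 1L)
    n0 <- 2L + rgeom(1, 1 / (1 + params$founding_extra_mean))
    doms <- sample(pool, sample(1:2, 1))
    fams[[fid]] <- list(id = fid, birth_node = root, deaths = integer(0),
                        n0 = n0, domains = doms,
                        dom_attach = rep(root, length(doms)),
                        shuffled = FALSE)
    gstores[[fid]] <- newGeneStore()
    proteins[[fid]] <- data.frame(protein = character(0),
                                  species = character(0),
                                  stringsAsFactors = FALSE)
    ev[root, "fam_birth"] <- ev[root, "fam_birth"] + 1L
    if (n0 > 1L) ev[root, "dup"] <- ev[root, "dup"] + (n0 - 1L)
    gs <- gstores[[fid]]
    topid <- gsAdd(gs, 0L, 0)
    cur <- topid
    attachv <- integer(0)
    for (k in seq_len(n0 - 1L)) {
      attachv <- c(attachv, cur)
      if (k < n0 - 1L) cur <- gsAdd(gs, cur, params$founding_eps)
    }
    attachv <- c(attachv, cur)
    if (n0 == 2L) attachv <- c(topid, topid)
    for (a in attachv) {
      s <- gsAdd(gs, a, params$founding_eps)   # speciation node at the root
      open[[root]][[fid]] <- c(open[[root]][[fid]], list(c(s, 0)))
    }
  }

  # ---- preorder sweep over branches ----
  for (v in preord) {
    p <- par[v]
    l <- len[v]
    entering <- aliveAt(p)
    n_alive <- length(entering)
    # family deaths (decided before members evolve on this branch)
    nd <- rpois(1, params$fam_death_rate * l * n_alive)
    if (nd > 0 && n_alive > 0) {
      cand <- sample(entering, min(nd, n_alive))
      for (fid in cand) {
        if (deathAllowed(fid, v)) {
          fams[[fid]]$deaths <- c(fams[[fid]]$deaths, v)
          ev[v, "fam_death"] <- ev[v, "fam_death"] + 1L
        }
      }
    }
    survivors <- setdiff(entering, names(Filter(function(f)
      v %in% f$deaths, fams)))
    # member evolution for surviving families
    for (fid in survivors) {
      before <- ev[v, "dup"]
      for (ln in open[[p]][[fid]])
        evolveSegment(fid, as.integer(ln[1]), ln[2], 0, v)
      noteDups(fid, v, before, ev[v, "dup"])
    }
    # family births on this branch
    nb <- rpois(1, params$fam_birth_rate * l * max(n_alive, 1))
    for (k in seq_len(nb)) {
      u <- runif(1, 0, l)
      before <- ev[v, "dup"]
      fid <- foundFamily(v, u, survivors)
      noteDups(fid, v, before, ev[v, "dup"])
    }
    # standalone domain births, appended to an existing surviving family
    ndb <- rpois(1, params$dom_birth_rate * l)
    for (k in seq_len(ndb)) {
      if (length(survivors) == 0) break
      fid <- sample(survivors, 1)
      d <- newDomain(v)
      fams[[fid]]$domains <- c(fams[[fid]]$domains, d)
      fams[[fid]]$dom_attach <- c(fams[[fid]]$dom_attach, v)
    }
  }

  # ---- collect outputs ----
  prot_df <- do.call(rbind, c(proteins, list(
    data.frame(protein = character(0), species = character(0),
               stringsAsFactors = FALSE))))
  fam_of <- setNames(rep(names(proteins), vapply(proteins, nrow, 0L)),
                     prot_df$protein)
  newicks <- lapply(gstores, gsNewick)
  bt <- branchTable(tree)
  truth_events <- rbind(
    data.frame(lineage = canonicalNodeName(tree, root), node = root,
               length = NA_real_, stringsAsFactors = FALSE),
    bt[, c("lineage", "node", "length")])
  truth_events <- cbind(truth_events, as.data.frame(ev[truth_events$node, ]))
  rownames(truth_events) <- NULL
  # births of families still observable at the leaves (>= 2 extant members;
  # a family reduced to one survivor by member deletion is not a family by
  # the >= 2-member definition and no clustering can recover it)
  detectable <- vapply(fams, function(f) nrow(proteins[[f$id]]) >= 2L, TRUE)
  det_birth <- tabulate(vapply(fams[detectable], `[[`, 0L, "birth_node"),
                        nbins = nn)
  truth_events$fam_birth_detectable <- det_birth[truth_events$node]

  fam_info <- do.call(rbind, lapply(fams, function(f) data.frame(
    family = f$id,
    birth_lineage = canonicalNodeName(tree, f$birth_node),
    n_death = length(f$deaths),
    death_lineages = paste(canonicalNodeName(tree, f$deaths), collapse = ";"),
    n0 = f$n0, shuffled = f$shuffled,
    domains = paste(f$domains, collapse = ";"),
    stringsAsFactors = FALSE)))
  rownames(fam_info) <- NULL

  pres_pairs <- data.frame(character = fam_of[prot_df$protein],
                           species = prot_df$species,
                           stringsAsFactors = FALSE)

  # domain hits: every protein carries its family's architecture applicable
  # to its species, laid out head-to-tail with 100-residue domains
  hit_rows <- list()
  for (fid in names(fams)) {
    f <- fams[[fid]]
    pr <- proteins[[fid]]
    if (nrow(pr) == 0) next
    for (i in seq_len(nrow(pr))) {
      sp_tip <- match(pr$species[i], tree$tip.label)
      keep <- vapply(f$dom_attach, function(a)
        a == root || pr$species[i] %in% tu[[a]], TRUE)
      ds <- f$domains[keep]
      if (length(ds) == 0) next
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        protein = pr$protein[i], domain = ds,
        start = 100L * (seq_along(ds) - 1L) + 1L,
        end = 100L * seq_along(ds),
        score = 100, evalue = 1e-20, stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, c(hit_rows, list(data.frame(
    protein = character(0), domain = character(0), start = integer(0),
    end = integer(0), score = numeric(0), evalue = numeric(0),
    stringsAsFactors = FALSE))))

  # similarity edges: complete within-family graphs, then noise
  edge_rows <- list()
  dms <- list()
  for (fid in names(fams)) {
    nk <- newicks[[fid]]
    pr <- proteins[[fid]]
    if (is.null(nk) || nrow(pr) < 2) next
    gt <- parseNewick(nk)
    D <- ape::cophenetic.phylo(gt)
    if (params$dist_noise_sd > 0) {
      nz <- matrix(rnorm(length(D), 0, params$dist_noise_sd), nrow(D))
      nz <- (nz + t(nz)) / 2
      diag(nz) <- 0
      D <- pmax(D + nz, 0)
    }
    dms[[fid]] <- D
    cmb <- utils::combn(rownames(D), 2)
    w <- pmax(200 - 15 * D[cbind(cmb[1, ], cmb[2, ])], 10)
    edge_rows[[fid]] <- data.frame(from = cmb[1, ], to = cmb[2, ],
                                   weight = w, stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, c(edge_rows, list(data.frame(
    from = character(0), to = character(0), weight = numeric(0),
    stringsAsFactors = FALSE))))
  rownames(edges) <- NULL
  if (nrow(edges) > 0 && params$edge_drop > 0)
    edges <- edges[runif(nrow(edges)) >= params$edge_drop, , drop = FALSE]
  if (nrow(edges) > 0 && params$edge_false > 0) {
    nf <- rpois(1, params$edge_false * nrow(edges))
    if (nf > 0 && nrow(prot_df) >= 2) {
      fr <- sample(prot_df$protein, nf, replace = TRUE)
      to <- sample(prot_df$protein, nf, replace = TRUE)
      ok <- fr != to
      edges <- rbind(edges, data.frame(from = fr[ok], to = to[ok],
                                       weight = runif(sum(ok), 5, 15),
                                       stringsAsFactors = FALSE))
    }
  }

  list(
    dataset = list(proteins = prot_df, edges = edges, hits = hits,
                   distances = dms, gene_trees = newicks,
                   annotations = data.frame(protein = character(0),
                                            term = character(0),
                                            stringsAsFactors = FALSE),
                   obo = NULL, tree = tree, params = params, seed = seed),
    truth = list(events = truth_events, families = fam_info,
                 presence_pairs = pres_pairs,
                 family_of = fam_of,
                 dom_origin = dom_origin))
}

#' Plant a term enrichment into a simulated dataset
#'
#' Families whose true birth branch matches `branch` have one member
#' annotated with `term` with probability `effect`; every family gets each
#' background term with probability `base_rate`. A small ontology (a root
#' biological-process-style term with flat children) is attached when the
#' dataset has none.
#'
#' @param sim Result of [simulateFamDom()].
#' @param term Term ID to plant (added to the mini ontology if new).
#' @param branch Canonical lineage name of the target birth branch.
#' @param effect Annotation probability for target families.
#' @param base_rate Background annotation probability (default 0.01).
#' @param n_background_terms Background term count (default 8).
#' @return `sim` with `dataset$annotations` and `dataset$obo` filled in.
#' @export
plantEnrichment <- function(sim, term, branch, effect, base_rate = 0.01,
                            n_background_terms = 8L) {
  fam_info <- sim$truth$families
  if (!branch %in% fam_info$birth_lineage &&
      !branch %in% canonicalNodeName(sim$dataset$tree,
        seq_len(ape::Ntip(sim$dataset$tree) + sim$dataset$tree$Nnode)))
    stop("unknown branch: ", branch)
  bg_terms <- sprintf("T:%07d", seq_len(n_background_terms))
  all_terms <- unique(c(term, bg_terms))
  root_term <- "T:0000000"
  obo <- c("format-version: 1.2", "",
           "[Term]", paste0("id: ", root_term), "name: biological process", "")
  for (t in all_terms)
    obo <- c(obo, "[Term]", paste0("id: ", t),
             paste0("name: synthetic process ", t),
             paste0("is_a: ", root_term, " ! biological process"), "")
  first_prot <- function(fid) {
    pr <- sim$dataset$proteins
    fams <- sim$truth$family_of
    p <- pr$protein[fams[pr$protein] == fid]
    if (length(p)) p[1] else NA_character_
  }
  ann <- list()
  for (i in seq_len(nrow(fam_info))) {
    fid <- fam_info$family[i]
    p <- first_prot(fid)
    if (is.na(p)) next
    if (fam_info$birth_lineage[i] == branch && runif(1) < effect)
      ann[[length(ann) + 1L]] <- data.frame(protein = p, term = term,
                                            stringsAsFactors = FALSE)
    for (t in bg_terms) if (runif(1) < base_rate)
      ann[[length(ann) + 1L]] <- data.frame(protein = p, term = t,
                                            stringsAsFactors = FALSE)
  }
  sim$dataset$annotations <- do.call(rbind, c(ann, list(data.frame(
    protein = character(0), term = character(0), stringsAsFactors = FALSE))))
  sim$dataset$obo <- obo
  sim$dataset$planted <- list(term = term, branch = branch, effect = effect,
                              base_rate = base_rate)
  sim
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits the ABC similarity edge list, the 6-column domain hit TSV, the
#' protein-to-species map, one PHYLIP square distance matrix per family
#' with >= 2 members, the species tree Newick, the annotation TSV and mini
#' OBO when present, and the ground truth as JSON.
#'
#' @param sim Result of [simulateFamDom()] (optionally after
#'   [plantEnrichment()]).
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
emitDataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "dist"), showWarnings = FALSE)
  ds <- sim$dataset
  write.table(ds$edges, file.path(outdir, "edges.abc"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(ds$hits, file.path(outdir, "domain_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(ds$proteins, file.path(outdir, "protein_species.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(writeNewick(ds$tree), file.path(outdir, "species_tree.nwk"))
  for (fid in names(ds$distances))
    writePhylipDist(ds$distances[[fid]],
                    file.path(outdir, "dist", paste0(fid, ".phy")))
  if (nrow(ds$annotations) > 0)
    write.table(ds$annotations, file.path(outdir, "annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  if (!is.null(ds$obo)) writeLines(ds$obo, file.path(outdir, "mini.obo"))
  truth <- sim$truth
  jsonlite::write_json(
    list(events = truth$events, families = truth$families,
         dom_origin = as.list(truth$dom_origin), seed = ds$seed),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
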