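# Stoichiometric network container and readers (TSV dialect, minimal SBML L3).

#' Construct a stoichiometric network
#'
#' Builds the network container used by [solve_fba()]. Reactions carry a
#' named stoichiometry vector (metabolite id -> signed coefficient,
#' negative = consumed), a reversibility flag and role flags. The
#' metabolite x reaction stoichiometric matrix S is assembled column by
#' column; steady-state mass balance is `S %*% v = 0`.
#'
#' @param metabolites data.frame with columns `id`, `name`, `extracellular`
#'   (logical: member of the tracked extracellular set, or biomass/product).
#' @param reactions list of reactions; each a list with fields `id`,
#'   `stoichiometry` (named numeric), `reversible`, `is_exchange`,
#'   `is_biomass`, `is_product` (logicals).
#' @return Object of class `flux_network` with elements `metabolites`,
#'   `reactions` and the dense matrix `S` (rows = metabolites in input
#'   order, columns = reactions in input order).
#' @export
flux_network <- function(metabolites, reactions) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "extracellular") %in% names(metabolites)))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  met_ids <- as.character(metabolites$id)
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite id: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction id: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  S <- matrix(0, nrow = length(met_ids), ncol = length(reactions),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    st <- r$stoichiometry
    if (length(st) == 0L)
      stop("reaction '", r$id, "' has empty stoichiometry")
    if (any(!is.finite(st)) || any(st == 0))
      stop("reaction '", r$id, "' has non-finite or zero coefficients")
    unknown <- setdiff(names(st), met_ids)
    if (length(unknown))
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    S[names(st), j] <- st
  }
  for (fl in c("reversible", "is_exchange", "is_biomass", "is_product"))
    reactions <- lapply(reactions, function(r) {
      if (is.null(r[[fl]])) r[[fl]] <- FALSE
      r
    })
  n_bio <- sum(vapply(reactions, `[[`, NA, "is_biomass"))
  if (n_bio != 1L)
    stop("network must contain exactly one biomass reaction (found ", n_bio, ")")
  structure(list(metabolites = metabolites, reactions = reactions, S = S),
            class = "flux_network")
}

reaction_field <- function(net, field) {
  vapply(net$reactions, `[[`, logical(1), field)
}

reaction_ids <- function(net) vapply(net$reactions, `[[`, "", "id")

biomass_id <- function(net) reaction_ids(net)[reaction_field(net, "is_biomass")]

#' Exchange reactions of the tracked extracellular metabolites
#'
#' Maps each extracellular metabolite to its single exchange reaction.
#' Written with the boundary convention `met ->`, so a positive exchange
#' flux is secretion and a negative one is uptake.
#'
#' @param net A `flux_network`.
#' @return Named character vector: metabolite id -> exchange reaction id.
#' @export
exchange_map <- function(net) {
  ex <- which(reaction_field(net, "is_exchange"))
  out <- character(0)
  for (j in ex) {
    st <- net$reactions[[j]]$stoichiometry
    if (length(st) == 1L)
      out[names(st)] <- net$reactions[[j]]$id
  }
  out
}

parse_equation <- function(eq, id, line = NA) {
  where <- if (is.na(line)) "" else paste0(" (line ", line, ")")
  reversible <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) > 2L || !grepl("->", eq, fixed = TRUE))
    stop("cannot parse reaction equation for '", id, "'", where, ": ", eq)
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(numeric(0))
    if (grepl("^\\+|\\+$", side) || grepl("\\+[[:space:]]*\\+", side))
      stop("dangling '+' in equation for '", id, "'", where)
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    st <- numeric(0)
    for (term in terms) {
      if (term == "")
        stop("empty term in equation for '", id, "'", where)
      toks <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(toks) == 1L) {
        coef <- 1; met <- toks[1]
      } else if (length(toks) == 2L &&
                 grepl("^[0-9.eE+-]+$", toks[1]) &&
                 !is.na(suppressWarnings(as.numeric(toks[1])))) {
        coef <- as.numeric(toks[1]); met <- toks[2]
      } else stop("cannot parse term '", term, "' in equation for '", id,
                  "'", where)
      st[met] <- (if (is.na(st[met])) 0 else st[met]) + sign * coef
    }
    st
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- if (length(sides) == 2L) parse_side(sides[2], +1) else numeric(0)
  st <- lhs
  for (m in names(rhs)) st[m] <- (if (is.na(st[m])) 0 else st[m]) + rhs[m]
  st <- st[st != 0]
  list(stoichiometry = st, reversible = reversible)
}

#' Read a stoichiometric network from TSV or SBML
#'
#' TSV dialect: tab-separated with header
#' `id  equation  reversible  exchange  biomass  product`, one reaction per
#' row. Equations use `A + 2 B -> C` (`<->` marks a reversible reaction);
#' an empty side denotes a boundary (exchange or sink) reaction.
#' Metabolites are collected in first-appearance order; extracellular
#' status is inferred from exchange membership. SBML: Level 3 core
#' (species, reactions, reversible attribute), biomass identified through
#' the active fbc objective when present, else by reaction id matching
#' "biomass"/"growth"; exchange reactions are single-metabolite boundary
#' reactions.
#'
#' @param path File path.
#' @param format `"tsv"`, `"sbml"`, or `"auto"` (by file extension).
#' @return A validated [flux_network()], reactions in file order.
#' @export
read_network <- function(path, format = c("auto", "tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "tsv"
  net <- if (format == "tsv") read_network_tsv(path) else read_network_sbml(path)
  bad <- validate_network(net)
  if (length(bad))
    warning("network loaded with findings: ", paste(bad, collapse = "; "))
  net
}

as_flag <- function(x, col, line) {
  x <- tolower(trimws(as.character(x)))
  if (x %in% c("1", "true", "yes", "y")) return(TRUE)
  if (x %in% c("0", "false", "no", "n", "", "na")) return(FALSE)
  stop("cannot parse flag '", x, "' in column ", col, " (line ", line, ")")
}

read_network_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           strip.white = TRUE, comment.char = "#")
  need <- c("id", "equation")
  if (!all(need %in% names(tab)))
    stop("network TSV must have columns id and equation: ", path)
  for (col in c("reversible", "exchange", "biomass", "product"))
    if (is.null(tab[[col]])) tab[[col]] <- FALSE
  reactions <- vector("list", nrow(tab))
  met_order <- character(0)
  for (i in seq_len(nrow(tab))) {
    pe <- parse_equation(tab$equation[i], tab$id[i], line = i + 1L)
    reactions[[i]] <- list(
      id = as.character(tab$id[i]),
      stoichiometry = pe$stoichiometry,
      reversible = pe$reversible || as_flag(tab$reversible[i], "reversible", i + 1L),
      is_exchange = as_flag(tab$exchange[i], "exchange", i + 1L),
      is_biomass = as_flag(tab$biomass[i], "biomass", i + 1L),
      is_product = as_flag(tab$product[i], "product", i + 1L))
    met_order <- union(met_order, names(pe$stoichiometry))
  }
  ex_mets <- unlist(lapply(reactions, function(r)
    if (r$is_exchange && length(r$stoichiometry) == 1L) names(r$stoichiometry)))
  mets <- data.frame(id = met_order, name = met_order,
                     extracellular = met_order %in% ex_mets,
                     stringsAsFactors = FALSE)
  flux_network(mets, reactions)
}

read_network_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns_all <- xml2::xml_ns(doc)
  sp <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  met_ids <- xml2::xml_attr(sp, "id")
  met_names <- xml2::xml_attr(sp, "name")
  met_names[is.na(met_names)] <- met_ids[is.na(met_names)]
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  keep <- !boundary
  rx <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  # active fbc objective -> biomass reaction
  obj_rxn <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[local-name()='fluxObjective']"), "reaction")
  reactions <- vector("list", length(rx))
  for (j in seq_along(rx)) {
    node <- rx[[j]]
    rid <- xml2::xml_attr(node, "id")
    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(
        node, paste0("./*[local-name()='", tag,
                     "']/*[local-name()='speciesReference']"))
      ids <- xml2::xml_attr(refs, "species")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      keep_ref <- !(ids %in% met_ids[boundary])
      st <- sign * coef[keep_ref]
      names(st) <- ids[keep_ref]
      st
    }
    st <- c(get_side("listOfReactants", -1), get_side("listOfProducts", +1))
    st <- tapply(st, names(st), sum)
    st <- st[st != 0]
    st2 <- as.numeric(st); names(st2) <- names(st)
    reactions[[j]] <- list(
      id = rid, stoichiometry = st2,
      reversible = xml2::xml_attr(node, "reversible") %in% "true",
      is_exchange = length(st2) == 1L,
      is_biomass = (rid %in% obj_rxn) ||
        (length(obj_rxn) == 0L && grepl("biomass|growth", rid, ignore.case = TRUE)),
      is_product = grepl("product|mab|igg", rid, ignore.case = TRUE) &&
        length(st2) >= 1L)
  }
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  ord <- met_ids[keep][met_ids[keep] %in% used]
  ex_mets <- unlist(lapply(reactions, function(r)
    if (r$is_exchange) names(r$stoichiometry)))
  mets <- data.frame(id = ord, name = met_names[keep][met_ids[keep] %in% used],
                     extracellular = ord %in% ex_mets,
                     stringsAsFactors = FALSE)
  flux_network(mets, reactions)
}

#' Validate a stoichiometric network
#'
#' Returns findings (not errors): orphan metabolites appearing in no
#' reaction, dead-end metabolites that are only produced or only consumed
#' and have no exchange, duplicate exchange reactions for one metabolite,
#' and extracellular metabolites lacking an exchange reaction.
#'
#' @param net A `flux_network`.
#' @return Character vector of human-readable findings; empty if the
#'   network is clean.
#' @export
validate_network <- function(net) {
  findings <- character(0)
  S <- net$S
  orphan <- rownames(S)[rowSums(S != 0) == 0]
  for (m in orphan)
    findings <- c(findings, paste0("orphan metabolite '", m, "' appears in no reaction"))
  # exchange multiplicity
  ex <- which(reaction_field(net, "is_exchange"))
  ex_met <- unlist(lapply(net$reactions[ex], function(r)
    if (length(r$stoichiometry) == 1L) names(r$stoichiometry)))
  dup <- unique(ex_met[duplicated(ex_met)])
  for (m in dup)
    findings <- c(findings, paste0("duplicate exchange reactions for metabolite '", m, "'"))
  for (m in net$metabolites$id[net$metabolites$extracellular])
    if (!m %in% ex_met)
      findings <- c(findings,
                    paste0("extracellular metabolite '", m, "' has no exchange reaction"))
  # dead ends: internal metabolite only produced or only consumed,
  # counting reversible reactions as bidirectional
  rev <- reaction_field(net, "reversible")
  for (i in seq_len(nrow(S))) {
    m <- rownames(S)[i]
    if (m %in% ex_met || m %in% orphan) next
    row <- S[i, ]
    can_produce <- any(row > 0) || any(row < 0 & rev)
    can_consume <- any(row < 0) || any(row > 0 & rev)
    if (!(can_produce && can_consume))
      findings <- c(findings, paste0("dead-end metabolite '", m, "'"))
  }
  findings
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("Stoichiometric network: %d metabolites x %d reactions\n",
              nrow(x$S), ncol(x$S)))
  cat(sprintf("  reversible: %d, exchange: %d, biomass: %s, product: %s\n",
              sum(reaction_field(x, "reversible")),
              sum(reaction_field(x, "is_exchange")),
              paste(reaction_ids(x)[reaction_field(x, "is_biomass")], collapse = ","),
              paste(reaction_ids(x)[reaction_field(x, "is_product")], collapse = ",")))
  invisible(x)
}

#' Write a network in the package TSV dialect
#'
#' @param net A `flux_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  fmt_num <- function(x) {
    s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
    sub("\\.?0+$", "", s)
  }
  eqs <- vapply(net$reactions, function(r) {
    st <- r$stoichiometry
    side <- function(sel, sgn) {
      if (!any(sel)) return("")
      paste(vapply(which(sel), function(k) {
        coef <- abs(st[k])
        if (coef == 1) names(st)[k]
        else paste(fmt_num(coef), names(st)[k])
      }, ""), collapse = " + ")
    }
    arrow <- if (r$reversible) "<->" else "->"
    trimws(paste(side(st < 0), arrow, side(st > 0)))
  }, "")
  tab <- data.frame(
    id = reaction_ids(net), equation = eqs,
    reversible = as.integer(reaction_field(net, "reversible")),
    exchange = as.integer(reaction_field(net, "is_exchange")),
    biomass = as.integer(reaction_field(net, "is_biomass")),
    product = as.integer(reaction_field(net, "is_product")))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
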