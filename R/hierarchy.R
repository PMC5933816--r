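#' Conserved protein-domain vocabulary for LTR retrotransposons
#'
#' The classifier's feature language is built over a two-level hierarchy of
#' conserved protein domains: 26 subdomains (CDD/Pfam profiles) grouped under
#' 7 general domains (RNase, Integrase, GAG, AP, RT, Pre-integrase, YR).
#' Domain hits name subdomains only; tests may refer to either level, with
#' the "is a subdomain of" relation supplied as background knowledge.
#'
#' @param path Path to a tab-separated vocabulary file with columns
#'   `general`, `subdomain`, `accession`. Defaults to the manifest shipped
#'   with the package.
#' @return An object of class `ltr_hierarchy`: a list with elements
#'   `subdomains` (character, length 26), `generals` (character, length 7),
#'   `parent` (named character mapping subdomain -> general), `accession`
#'   (named character mapping subdomain -> CDD/Pfam id), and `test_domains`
#'   (the extensionally distinct identifiers usable in node tests; generals
#'   with a single subdomain are extensionally identical to that subdomain
#'   and therefore excluded).
#' @export
ltr_hierarchy <- function(path = system.file("extdata", "domain_vocabulary.tsv",
                                             package = "ltrforest")) {
  voc <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  stopifnot(all(c("general", "subdomain", "accession") %in% names(voc)))
  if (anyDuplicated(voc$subdomain))
    stop("duplicate subdomain identifiers in vocabulary: ",
         paste(voc$subdomain[duplicated(voc$subdomain)], collapse = ", "))
  generals <- unique(voc$general)
  parent <- stats::setNames(voc$general, voc$subdomain)
  accession <- stats::setNames(voc$accession, voc$subdomain)
  n_children <- table(voc$general)[generals]
  # A general with exactly one subdomain matches exactly the hits its
  # subdomain matches; tests built on it are duplicates and are not enumerated.
  multi <- generals[n_children > 1L]
  h <- structure(list(
    subdomains   = voc$subdomain,
    generals     = generals,
    parent       = parent,
    accession    = accession,
    test_domains = c(voc$subdomain, multi)
  ), class = "ltr_hierarchy")
  h
}

#' @export
print.ltr_hierarchy <- function(x, ...) {
  cat("Domain hierarchy:", length(x$subdomains), "subdomains under",
      length(x$generals), "general domains;",
      length(x$test_domains), "extensionally distinct test domains\n")
  invisible(x)
}

.check_domain <- function(hierarchy, ids) {
  known <- c(hierarchy$subdomains, hierarchy$generals)
  bad <- setdiff(unique(ids), known)
  if (length(bad))
    stop("unknown domain identifier(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Domain subsumption
#'
#' `subsumes(h, q, s)` is TRUE iff a hit on subdomain `s` satisfies a test on
#' domain `q`: either `q == s`, or `q` is the general domain of which `s` is
#' a subdomain.
#'
#' @param hierarchy An `ltr_hierarchy`.
#' @param query_domain Domain named in a test (subdomain or general).
#' @param hit_subdomain Subdomain carried by a hit. Vectorised.
#' @return Logical vector.
#' @export
subsumes <- function(hierarchy, query_domain, hit_subdomain) {
  stopifnot(length(query_domain) == 1L)
  .check_domain(hierarchy, query_domain)
  .check_domain(hierarchy, hit_subdomain)
  if (any(!hit_subdomain %in% hierarchy$subdomains))
    stop("hit domain must be a subdomain, got: ",
         paste(setdiff(hit_subdomain, hierarchy$subdomains), collapse = ", "))
  query_domain == hit_subdomain |
    unname(hierarchy$parent[hit_subdomain]) == query_domain
}

# Integer code (position in test_domains) for each test domain a subdomain
# hit contributes to: its own code and, when distinct, its general's code.
.domain_codes <- function(hierarchy) {
  td <- hierarchy$test_domains
  own <- match(hierarchy$subdomains, td)
  gen <- match(unname(hierarchy$parent[hierarchy$subdomains]), td)  # NA if dropped
  list(own = stats::setNames(own, hierarchy$subdomains),
       gen = stats::setNames(gen, hierarchy$subdomains))
}
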