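# Hand-built fixtures and independent oracles shared across test files.

# Small hand-written network: 6 metabolites, 4 reactions (one boundary
# exchange, uncatalyzed), 3 genes; 3 mapping-eligible reactions.
#   r1: A + B -> C        [g1]
#   r2: C <-> D           [g2]   (reversible)
#   r3: D + E -> F        [g1, g3]
#   r4: F ->              []     (exchange)
toyModel <- function() {
  mets <- data.frame(id = c("A", "B", "C", "D", "E", "F"),
                     name = c("A", "B", "C", "D", "E", "F"),
                     compartment = "c", boundary = FALSE,
                     stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "r1", stoich = c(A = -1, B = -1, C = 1), reversible = FALSE,
         genes = c("g1")),
    list(id = "r2", stoich = c(C = -1, D = 1), reversible = TRUE,
         genes = c("g2")),
    list(id = "r3", stoich = c(D = -1, E = -1, F = 1), reversible = FALSE,
         genes = c("g1", "g3")),
    list(id = "r4", stoich = c(F = -1), reversible = FALSE,
         genes = character(0)))
  GEMModel(mets, rxns, c("g1", "g2", "g3"))
}

# Two-compartment variant exercising transport classification and
# compartment collapsing: ATP exists in cytosol and extracellular space.
compartmentModel <- function() {
  mets <- data.frame(
    id = c("atp_c", "atp_e", "glc_c", "pyr_c"),
    name = c("ATP", "ATP", "Glucose", "Pyruvate"),
    compartment = c("c", "e", "c", "c"), boundary = FALSE,
    stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "t1", stoich = c(atp_c = -1, atp_e = 1), reversible = FALSE,
         genes = c("tg1")),                       # catalyzed transporter
    list(id = "r1", stoich = c(glc_c = -1, atp_c = -1, pyr_c = 1),
         reversible = FALSE, genes = c("g1")),
    list(id = "ex1", stoich = c(atp_e = -1), reversible = FALSE,
         genes = character(0)))
  GEMModel(mets, rxns, c("tg1", "g1"))
}

# Minimal SBML L3 + fbc document: 3 species (one boundary), 2 gene
# products, nested Boolean GPR on r1, reversibility via flux bounds on r2.
writeTinySBML <- function(path) {
  writeLines(c(
'<?xml version="1.0" encoding="UTF-8"?>',
'<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
'      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
'      level="3" version="1" fbc:required="false">',
'  <model id="tiny" fbc:strict="true">',
'    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
'    <listOfParameters>',
'      <parameter id="lb_rev" value="-1000" constant="true"/>',
'      <parameter id="lb_irr" value="0" constant="true"/>',
'      <parameter id="ub" value="1000" constant="true"/>',
'    </listOfParameters>',
'    <listOfSpecies>',
'      <species id="M_a" name="Alpha" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>',
'      <species id="M_b" name="Beta" compartment="c" boundaryCondition="false" constant="false" hasOnlySubstanceUnits="false"/>',
'      <species id="M_x" name="Xboundary" compartment="c" boundaryCondition="true" constant="false" hasOnlySubstanceUnits="false"/>',
'    </listOfSpecies>',
'    <fbc:listOfGeneProducts>',
'      <fbc:geneProduct fbc:id="G_e1" fbc:label="ENZ1"/>',
'      <fbc:geneProduct fbc:id="G_e2" fbc:label="ENZ2"/>',
'    </fbc:listOfGeneProducts>',
'    <listOfReactions>',
'      <reaction id="R_r1" reversible="false" fbc:lowerFluxBound="lb_irr" fbc:upperFluxBound="ub" fast="false">',
'        <listOfReactants><speciesReference species="M_a" stoichiometry="2" constant="true"/></listOfReactants>',
'        <listOfProducts><speciesReference species="M_b" stoichiometry="1" constant="true"/></listOfProducts>',
'        <fbc:geneProductAssociation>',
'          <fbc:or>',
'            <fbc:geneProductRef fbc:geneProduct="G_e1"/>',
'            <fbc:and><fbc:geneProductRef fbc:geneProduct="G_e2"/><fbc:geneProductRef fbc:geneProduct="G_e1"/></fbc:and>',
'          </fbc:or>',
'        </fbc:geneProductAssociation>',
'      </reaction>',
'      <reaction id="R_r2" fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="ub" fast="false" reversible="true">',
'        <listOfReactants><speciesReference species="M_b" stoichiometry="1" constant="true"/></listOfReactants>',
'        <listOfProducts><speciesReference species="M_x" stoichiometry="1" constant="true"/></listOfProducts>',
'        <fbc:geneProductAssociation><fbc:geneProductRef fbc:geneProduct="G_e2"/></fbc:geneProductAssociation>',
'      </reaction>',
'    </listOfReactions>',
'  </model>',
'</sbml>'), path)
  path
}

# --- independent oracles -------------------------------------------------

# Exhaustive-enumeration hypergeometric upper tail: draw all C(N, n)
# subsets of the background and count those with >= k set members.
# Tractable for N <= 12; deliberately avoids phyper.
enumUpperTail <- function(N, K, n, k) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # members are labelled 1..K
  mean(hits >= k)
}

# Explicit choose()-sum upper tail (independent arithmetic route).
chooseTail <- function(N, K, n, k) {
  j <- k:min(n, K)
  if (k == 0) return(1)
  if (length(j) == 0 || min(n, K) < k) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Benjamini-Hochberg step-up recomputed from its definition.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Brute-force one-sided KS D+ against Uniform(0,1): sup over a fine grid
# of ECDF(t) - t.
dPlusGrid <- function(x, grid = seq(0, 1, length.out = 100000)) {
  ec <- stats::ecdf(x)
  max(ec(grid) - grid)
}
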