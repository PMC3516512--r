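#' The miniTLR fixture network
#'
#' A small, fully hand-checkable TLR-style signaling network used
#' throughout the test suite and documentation. It exercises every model
#' feature the analysis layer cares about:
#'
#' * three receptors (A: LPS-like, B: ssRNA-like, C: CpG-DNA-like), each
#'   with a ligand, a reversible exchange and a gene-gated binding
#'   reaction;
#' * a two-isozyme adaptor step (`201 or 202`, MyD88-style) feeding a
#'   shared ATP-coupled kinase cascade whose second step is a two-gene
#'   complex (`401 and 402`);
#' * five outputs: demand reactions for nuclear NF-kB, AP-1, CREB and IRF
#'   plus a vacuolar ROS demand; the AP-1 complex consumes two units of
#'   activated kinase (yield 0.5), and ROS branches off early with
#'   GTP-coupled stoichiometry (PHOX-style);
#' * an IRF output that requires co-stimulation: its complex-formation
#'   step consumes the receptor-proximal signals of receptors A *and* B;
#' * a CREB nuclear-export loop making the CREB binding reaction
#'   (`CREB_BIND`, itself usable as an output) carry baseline flux, plus
#'   one isolated internal 2-cycle;
#' * two orphan extracellular ligands whose binding reactions are blocked
#'   until dead-end patching adds their exchanges.
#'
#' The same network ships in the tabular dialect under
#' `inst/extdata/minitlr/` together with an expectations table computed by
#' an independent LP implementation (see `tools/minitlr_oracle.py`).
#'
#' @return A `sigflux_model`.
#' @export
mini_tlr <- function() {
  cp <- tibble::tribble(
    ~id,            ~name,                        ~compartment, ~role,
    "lpsA[e]",      "LPS-like ligand A",          "e", "ligand",
    "rnaB[e]",      "ssRNA-like ligand B",        "e", "ligand",
    "dnaC[e]",      "CpG-DNA-like ligand C",      "e", "ligand",
    "orphan1[e]",   "orphan ligand 1",            "e", "ligand",
    "orphan2[e]",   "orphan ligand 2",            "e", "ligand",
    "sigA[c]",      "receptor A proximal signal", "c", "receptor",
    "sigB[c]",      "receptor B proximal signal", "c", "receptor",
    "sigC[c]",      "receptor C proximal signal", "c", "receptor",
    "adap[c]",      "activated adaptor",          "c", "protein",
    "kin1[c]",      "activated kinase 1",         "c", "kinase",
    "kin2[c]",      "activated kinase 2",         "c", "kinase",
    "tfNFKB[c]",    "active NF-kB",               "c", "complex",
    "tfAP1[c]",     "active AP-1",                "c", "complex",
    "tfCREB[c]",    "active CREB",                "c", "complex",
    "tfIRF[c]",     "active IRF",                 "c", "complex",
    "nfkb[n]",      "nuclear NF-kB",              "n", "complex",
    "ap1[n]",       "nuclear AP-1",               "n", "complex",
    "creb[n]",      "nuclear CREB",               "n", "complex",
    "irf[n]",       "nuclear IRF",                "n", "complex",
    "ros[v]",       "reactive oxygen species",    "v", "metabolite",
    "atp[c]",       "ATP",                        "c", "metabolite",
    "adp[c]",       "ADP",                        "c", "metabolite",
    "gtp[c]",       "GTP",                        "c", "metabolite",
    "gdp[c]",       "GDP",                        "c", "metabolite",
    "loopx[c]",     "loop intermediate X",        "c", "protein",
    "loopy[c]",     "loop intermediate Y",        "c", "protein")

  rx <- tibble::tribble(
    ~id, ~formula, ~lb, ~ub, ~gpr, ~rclass,
    "EX_lpsA",   "lpsA[e] <=>",                          -1000, 1000, "",    "exchange",
    "EX_rnaB",   "rnaB[e] <=>",                          -1000, 1000, "",    "exchange",
    "EX_dnaC",   "dnaC[e] <=>",                          -1000, 1000, "",    "exchange",
    "EX_atp",    "atp[c] <=>",                           -1000, 1000, "",    "exchange",
    "EX_adp",    "adp[c] <=>",                           -1000, 1000, "",    "exchange",
    "EX_gtp",    "gtp[c] <=>",                           -1000, 1000, "",    "exchange",
    "EX_gdp",    "gdp[c] <=>",                           -1000, 1000, "",    "exchange",
    "BIND_A",    "lpsA[e] -> sigA[c]",                       0, 1000, "101", "binding",
    "BIND_B",    "rnaB[e] -> sigB[c]",                       0, 1000, "102", "binding",
    "BIND_C",    "dnaC[e] -> sigC[c]",                       0, 1000, "103", "binding",
    "BIND_O1",   "orphan1[e] -> sigA[c]",                    0, 1000, "104", "binding",
    "BIND_O2",   "orphan2[e] -> sigB[c]",                    0, 1000, "105", "binding",
    "SK_sigA",   "sigA[c] ->",                               0, 1000, "",    "sink",
    "SK_sigB",   "sigB[c] ->",                               0, 1000, "",    "sink",
    "SK_sigC",   "sigC[c] ->",                               0, 1000, "",    "sink",
    "ADAPT_A",   "sigA[c] + atp[c] -> adap[c] + adp[c]",     0, 1000, "201 or 202", "core",
    "ADAPT_B",   "sigB[c] + atp[c] -> adap[c] + adp[c]",     0, 1000, "201 or 202", "core",
    "ADAPT_C",   "sigC[c] + atp[c] -> adap[c] + adp[c]",     0, 1000, "201 or 202", "core",
    "KIN1",      "adap[c] + atp[c] -> kin1[c] + adp[c]",     0, 1000, "301 or 302 or 303", "core",
    "KIN2",      "kin1[c] + atp[c] -> kin2[c] + adp[c]",     0, 1000, "401 and 402", "core",
    "TF_NFKB",   "kin2[c] -> tfNFKB[c]",                     0, 1000, "501", "core",
    "TF_AP1",    "2 kin2[c] -> tfAP1[c]",                    0, 1000, "502 and 503", "core",
    "TF_CREB",   "kin2[c] -> tfCREB[c]",                     0, 1000, "504", "core",
    "TF_IRF",    "sigA[c] + sigB[c] + atp[c] -> tfIRF[c] + adp[c]", 0, 1000, "505", "core",
    "ROS_SYN",   "kin1[c] + gtp[c] -> ros[v] + gdp[c]",      0, 1000, "601 and 602", "core",
    "NFKB_TRANS", "tfNFKB[c] -> nfkb[n]",                    0, 1000, "",   "transport",
    "AP1_TRANS", "tfAP1[c] -> ap1[n]",                       0, 1000, "",   "transport",
    "CREB_BIND", "tfCREB[c] -> creb[n]",                     0, 1000, "",   "transport",
    "CREB_EXPORT", "creb[n] -> tfCREB[c]",                   0, 1000, "",   "transport",
    "IRF_TRANS", "tfIRF[c] -> irf[n]",                       0, 1000, "",   "transport",
    "DM_nfkb",   "nfkb[n] ->",                               0, 1000, "",   "demand",
    "DM_ap1",    "ap1[n] ->",                                0, 1000, "",   "demand",
    "DM_creb",   "creb[n] ->",                               0, 1000, "",   "demand",
    "DM_irf",    "irf[n] ->",                                0, 1000, "",   "demand",
    "DM_ros",    "ros[v] ->",                                0, 1000, "",   "demand",
    "LOOP_F",    "loopx[c] -> loopy[c]",                     0, 1000, "701", "core",
    "LOOP_R",    "loopy[c] -> loopx[c]",                     0, 1000, "",   "core")

  gn <- tibble::tribble(
    ~gene_id, ~symbol, ~description,
    "101", "TLRA",   "receptor A",
    "102", "TLRB",   "receptor B",
    "103", "TLRC",   "receptor C",
    "104", "TLRO1",  "orphan receptor 1",
    "105", "TLRO2",  "orphan receptor 2",
    "201", "ADAP1",  "adaptor isozyme 1",
    "202", "ADAP2",  "adaptor isozyme 2",
    "301", "KINA1",  "kinase-1 isozyme 1",
    "302", "KINA2",  "kinase-1 isozyme 2",
    "303", "KINA3",  "kinase-1 isozyme 3",
    "401", "KINB1",  "kinase-2 subunit 1",
    "402", "KINB2",  "kinase-2 subunit 2",
    "501", "NFKB1",  "NF-kB activator",
    "502", "FOSL",   "AP-1 subunit Fos-like",
    "503", "JUNL",   "AP-1 subunit Jun-like",
    "504", "CREB1",  "CREB activator",
    "505", "IRFL",   "IRF-like factor",
    "601", "PHOXA",  "oxidase subunit A",
    "602", "PHOXB",  "oxidase subunit B",
    "701", "LOOPG",  "loop enzyme")

  new_model(cp, rx, gn, id = "miniTLR")
}

#' Canonical I/O relationships of the miniTLR fixture
#'
#' One stimulation per receptor and output, plus the co-stimulation
#' (A together with B) required for the IRF output.
#'
#' @return A list with `pairs` (named list of [io_pair()] stimulations,
#'   one per input) and `outputs` (the output reaction ids:
#'   the four nuclear demands, the ROS demand and `CREB_BIND`).
#' @export
mini_tlr_io <- function() {
  outputs <- c("DM_nfkb", "DM_ap1", "DM_creb", "CREB_BIND", "DM_irf", "DM_ros")
  a <- io_pair("RA", "EX_lpsA", "BIND_A", "DM_nfkb")
  b <- io_pair("RB", "EX_rnaB", "BIND_B", "DM_nfkb")
  cc <- io_pair("RC", "EX_dnaC", "BIND_C", "DM_nfkb")
  ab <- io_pair("RA+RB", "EX_lpsA", "BIND_A", "DM_irf",
                co_stimulation = io_pair("RB", "EX_rnaB", "BIND_B", "DM_irf"))
  list(pairs = list(RA = a, RB = b, RC = cc, `RA+RB` = ab),
       outputs = outputs)
}
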