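#!/usr/bin/env python
"""Independent brute-force oracle for the miniTLR fixture.

Reads the fixture from inst/extdata/minitlr/, recomputes flux variability
ranges, blocked reactions, dead-end compounds, sub-network counts and
robustness curves with scipy.optimize.linprog (HiGHS), and writes
inst/extdata/minitlr/expectations.tsv. The R implementation is required to
reproduce every row of that table; this script shares no code with it.

Run from the repository root:  python tools/minitlr_oracle.py
"""
import csv
import re

import numpy as np
from scipy.optimize import linprog

FIX = "inst/extdata/minitlr"


def read_tsv(path):
    with open(path) as fh:
        return list(csv.DictReader(fh, delimiter="\t"))


def parse_formula(formula):
    arrow = "<=>" if "<=>" in formula else "->"
    lhs, _, rhs = formula.partition(arrow)
    stoich = {}
    for side, sign in ((lhs, -1), (rhs, 1)):
        for term in side.split("+"):
            term = term.strip()
            if not term:
                continue
            parts = term.split()
            coef = float(parts[0]) if len(parts) == 2 else 1.0
            cid = parts[-1]
            stoich[cid] = stoich.get(cid, 0.0) + sign * coef
    return stoich


class Model:
    def __init__(self):
        self.compounds = read_tsv(f"{FIX}/minitlr_compounds.tsv")
        rx = read_tsv(f"{FIX}/minitlr_reactions.tsv")
        self.rxn_ids = [r["id"] for r in rx]
        self.stoich = [parse_formula(r["formula"]) for r in rx]
        self.lb = np.array([float(r["lb"]) for r in rx])
        self.ub = np.array([float(r["ub"]) for r in rx])
        self.gpr = [r["gpr"] or "" for r in rx]
        self.rclass = [r["rclass"] for r in rx]
        self.cp_ids = [c["id"] for c in self.compounds]
        self.role = {c["id"]: c["role"] for c in self.compounds}
        self.S = np.zeros((len(self.cp_ids), len(self.rxn_ids)))
        for j, st in enumerate(self.stoich):
            for cid, coef in st.items():
                self.S[self.cp_ids.index(cid), j] = coef

    def idx(self, rid):
        return self.rxn_ids.index(rid)

    def optimize(self, rid, lb, ub, sense):
        c = np.zeros(len(self.rxn_ids))
        c[self.idx(rid)] = 1 if sense == "min" else -1
        res = linprog(c, A_eq=self.S, b_eq=np.zeros(self.S.shape[0]),
                      bounds=list(zip(lb, ub)), method="highs")
        if not res.success:
            return None
        return res.fun if sense == "min" else -res.fun

    def fva(self, rids, lb, ub):
        return {rid: (self.optimize(rid, lb, ub, "min"),
                      self.optimize(rid, lb, ub, "max")) for rid in rids}


def configure(m, pair, energy="sensitivity"):
    """pair: (exchange ids, binding ids) lists, or None for baseline."""
    lb, ub = m.lb.copy(), m.ub.copy()
    for j, rid in enumerate(m.rxn_ids):
        is_lig_ex = (m.rclass[j] == "exchange" and len(m.stoich[j]) == 1
                     and m.role[next(iter(m.stoich[j]))] == "ligand")
        if is_lig_ex or m.rclass[j] == "binding":
            lb[j] = ub[j] = 0.0
    if pair:
        for rid in pair[0]:
            lb[m.idx(rid)] = ub[m.idx(rid)] = -1.0
        for rid in pair[1]:
            lb[m.idx(rid)] = ub[m.idx(rid)] = 1.0
    if energy == "sensitivity":
        for rid in ("EX_atp", "EX_gtp"):
            lb[m.idx(rid)], ub[m.idx(rid)] = -25.0, 0.0
    return lb, ub


def dead_ends(m):
    out = []
    for i, cid in enumerate(m.cp_ids):
        prod = cons = False
        for j in range(len(m.rxn_ids)):
            coef = m.S[i, j]
            if coef == 0:
                continue
            fwd, bwd = m.ub[j] > 1e-9, m.lb[j] < -1e-9
            if (coef > 0 and fwd) or (coef < 0 and bwd):
                prod = True
            if (coef < 0 and fwd) or (coef > 0 and bwd):
                cons = True
        if not (prod and cons):
            out.append(cid)
    return out


def main():
    m = Model()
    rows = []

    outputs = ["DM_nfkb", "DM_ap1", "DM_creb", "CREB_BIND", "DM_irf", "DM_ros"]
    stims = {
        "baseline": None,
        "RA": (["EX_lpsA"], ["BIND_A"]),
        "RB": (["EX_rnaB"], ["BIND_B"]),
        "RC": (["EX_dnaC"], ["BIND_C"]),
        "RA+RB": (["EX_lpsA", "EX_rnaB"], ["BIND_A", "BIND_B"]),
    }
    for label, pair in stims.items():
        lb, ub = configure(m, pair)
        for rid, (lo, hi) in m.fva(outputs, lb, ub).items():
            rows.append(("fva", label, rid, "min", f"{lo:.10g}"))
            rows.append(("fva", label, rid, "max", f"{hi:.10g}"))

    full = m.fva(m.rxn_ids, m.lb, m.ub)
    for rid, (lo, hi) in full.items():
        if abs(lo) <= 1e-6 and abs(hi) <= 1e-6:
            rows.append(("blocked", "shipped", rid, "blocked", "1"))

    for cid in dead_ends(m):
        rows.append(("dead_end", "shipped", cid, "dead_end", "1"))

    # sub-network counts induced by gene sets (token match on GPR strings)
    for label, genes in (("ap1_complex", {"502", "503"}),
                         ("up_set", {"201", "501", "502", "503"})):
        rids = [m.rxn_ids[j] for j in range(len(m.rxn_ids))
                if genes & set(re.findall(r"[\w.]+", m.gpr[j]))]
        cps = sorted({cid for rid in rids for cid in m.stoich[m.idx(rid)]})
        rows.append(("subnet", label, "n_reactions", "count", str(len(rids))))
        rows.append(("subnet", label, "n_compounds", "count", str(len(cps))))

    # robustness curves: 50-point energy scans under receptor-A stimulation
    curves = {
        "RA_DM_nfkb_atp": ("RA", "DM_nfkb", "EX_atp"),
        "RA_DM_nfkb_gtp": ("RA", "DM_nfkb", "EX_gtp"),
        "RA_DM_ros_gtp": ("RA", "DM_ros", "EX_gtp"),
    }
    grid = np.linspace(-25.0, 0.0, 50)
    for label, (stim, out, ctrl) in curves.items():
        lb, ub = configure(m, stims[stim])
        for k, g in enumerate(grid):
            lb2, ub2 = lb.copy(), ub.copy()
            lb2[m.idx(ctrl)], ub2[m.idx(ctrl)] = g, 0.0
            val = m.optimize(out, lb2, ub2, "max")
            rows.append(("curve", label, f"{k:02d}", f"{g:.10g}",
                         "NA" if val is None else f"{val:.10g}"))

    with open(f"{FIX}/expectations.tsv", "w", newline="") as fh:
        w = csv.writer(fh, delimiter="\t", lineterminator="\n")
        w.writerow(["section", "scenario", "id", "key", "value"])
        w.writerows(rows)
    print(f"wrote {len(rows)} expectation rows")


if __name__ == "__main__":
    main()
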