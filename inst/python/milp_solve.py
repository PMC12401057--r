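"""MILP bridge: solve a batch of models with scipy.optimize.milp (HiGHS).

Usage: python milp_solve.py <in.json> <out.json>

Input JSON: {"models": [{n_vars, n_rows, obj, lb, ub, ai, aj, av,
                          rlb, rub, time_limit, mip_gap}, ...]}
All variables are integer.  Bounds with magnitude >= 1e29 mean +/-infinity.
Output JSON: [{"status": "optimal"|"infeasible"|"timeout"|"error",
               "objective": float, "x": [..]}, ...]
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import milp, LinearConstraint, Bounds


def definf(a):
    a = np.asarray(a, dtype=float)
    a[a >= 1e29] = np.inf
    a[a <= -1e29] = -np.inf
    return a


def solve_one(m):
    n = int(m["n_vars"])
    c = np.asarray(m["obj"], dtype=float)
    lb, ub = definf(m["lb"]), definf(m["ub"])
    constraints = []
    nrows = int(m["n_rows"])
    if nrows > 0:
        A = sparse.csc_matrix(
            (np.asarray(m["av"], dtype=float),
             (np.asarray(m["ai"], dtype=int), np.asarray(m["aj"], dtype=int))),
            shape=(nrows, n))
        constraints = [LinearConstraint(A, definf(m["rlb"]), definf(m["rub"]))]
    res = milp(c, constraints=constraints,
               integrality=np.ones(n),
               bounds=Bounds(lb, ub),
               options={"time_limit": float(m.get("time_limit", 600)),
                        "mip_rel_gap": float(m.get("mip_gap", 0))})
    if res.status == 0:
        return {"status": "optimal", "objective": float(res.fun),
                "x": [float(v) for v in res.x]}
    if res.status == 2:
        return {"status": "infeasible", "objective": None, "x": None}
    if res.status == 1:
        return {"status": "timeout", "objective": None, "x": None}
    return {"status": "error", "objective": None, "x": None}


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    out = []
    for m in payload["models"]:
        try:
            out.append(solve_one(m))
        except Exception as exc:  # report, keep batch going
            out.append({"status": "error", "objective": None, "x": None,
                        "message": str(exc)})
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
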