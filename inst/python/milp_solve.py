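"""Batch MILP solve via scipy.optimize.milp (HiGHS backend).

Reads a JSON document {"models": [...]} and writes a JSON list of results.
Each model: c, A (dense row-major list of rows), row_lb, row_ub, lb, ub,
integrality, optional time_limit (seconds). Infinities are encoded as the
sentinel +/-1e30 by the caller.

Usage: python milp_solve.py input.json output.json
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp

SENTINEL = 1e29


def decode_inf(values):
    a = np.asarray(values, dtype=float)
    a[a >= SENTINEL] = np.inf
    a[a <= -SENTINEL] = -np.inf
    return a


STATUS = {0: "optimal", 1: "time_limit", 2: "infeasible",
          3: "unbounded", 4: "error"}


def solve_one(m):
    c = np.asarray(m["c"], dtype=float)
    A = np.asarray(m["A"], dtype=float).reshape(-1, c.size)
    constraints = LinearConstraint(A, decode_inf(m["row_lb"]),
                                   decode_inf(m["row_ub"]))
    bounds = Bounds(decode_inf(m["lb"]), decode_inf(m["ub"]))
    integrality = np.asarray(m["integrality"], dtype=int)
    options = {"mip_rel_gap": 0.0}
    if m.get("time_limit") is not None:
        options["time_limit"] = float(m["time_limit"])
    res = milp(c=c, constraints=constraints, bounds=bounds,
               integrality=integrality, options=options)
    out = {"status": STATUS.get(res.status, "error"),
           "message": res.message}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["objective"] = float(res.fun)
        out["gap"] = float(res.mip_gap) if res.mip_gap is not None else None
    return out


def main(argv):
    with open(argv[1]) as fh:
        doc = json.load(fh)
    results = []
    for m in doc["models"]:
        try:
            results.append(solve_one(m))
        except Exception as exc:  # surface per-model failures to the caller
            results.append({"status": "error", "message": str(exc)})
    with open(argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(sys.argv)
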