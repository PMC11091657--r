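"""Solve min c'x s.t. A x = b, lb <= x <= ub with SciPy's HiGHS.

Reads a JSON problem (sparse triplets) on stdin, writes a JSON solution on
stdout.  Used by the R package as an independent LP backend for
cross-checking the built-in simplex.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog
from scipy.sparse import coo_matrix


def main():
    p = json.load(sys.stdin)

    def scalar(v):
        return v[0] if isinstance(v, list) else v

    m, n = int(scalar(p["m"])), int(scalar(p["n"]))
    A = coo_matrix((p["x"], (p["i"], p["j"])), shape=(m, n)).tocsr()
    lb = [(-np.inf if v is None else v) for v in p["lb"]]
    ub = [(np.inf if v is None else v) for v in p["ub"]]
    res = linprog(c=p["obj"], A_eq=A, b_eq=p["b"],
                  bounds=list(zip(lb, ub)), method="highs")
    status = {0: "optimal", 1: "maxiter", 2: "infeasible", 3: "unbounded"}.get(
        res.status, "error")
    out = {"status": status}
    if status == "optimal":
        out["x"] = list(map(float, res.x))
        out["objective"] = float(res.fun)
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
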