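"""Independent LP oracle: solve min c'x, A x = b, lb <= x <= ub with HiGHS.

Reads a JSON list of cases, writes a JSON list of {status, fun}.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog

cases = json.load(open(sys.argv[1]))
out = []
for cs in cases:
    A = np.atleast_2d(np.array(cs["A"], dtype=float))
    res = linprog(np.array(cs["c"], dtype=float),
                  A_eq=A, b_eq=np.array(cs["b"], dtype=float),
                  bounds=list(zip(cs["lb"], cs["ub"])), method="highs")
    if res.status == 0:
        out.append({"status": "optimal", "fun": res.fun})
    elif res.status == 2:
        out.append({"status": "infeasible"})
    else:
        out.append({"status": "other:%d" % res.status})
json.dump(out, open(sys.argv[2], "w"))
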