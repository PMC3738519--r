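#!/usr/bin/env python
"""Convert the study's MAT-container layout to the native CSV dialect.

Usage: mat_to_native.py <input.mat> <output_dir>

Expected container: one top-level struct variable whose fields are the
participants; each participant struct holds a 26 x 60 cell array of
reaction times (condition order: catch, auditory-only, SOAs -400..+400
ascending, visual-only; Inf = miss) and a 23 x 3 numeric TOJ array
(SOA, visual-first count, total trials). Field names are not assumed;
arrays are identified by shape. Errors name the offending field.
"""
import csv
import math
import sys

import numpy as np
from scipy.io import loadmat

SOAS = [-400, -300, -250, -200, -150, -120, -100, -80, -60, -40, -20,
        0, 20, 40, 60, 80, 100, 120, 150, 200, 250, 300, 400]
CONDITIONS = [("catch", "")] + [("auditory_only", "")] + \
    [("av", str(s)) for s in SOAS] + [("visual_only", "")]


def fail(msg):
    sys.stderr.write("mat_to_native: " + msg + "\n")
    sys.exit(1)


def cell_latencies(row):
    out = []
    for entry in np.ravel(row):
        arr = np.asarray(entry, dtype=float).ravel()
        for v in arr:
            if np.isnan(v):
                continue
            out.append(v)
    return out


def main(mat_path, out_dir):
    mat = loadmat(mat_path, squeeze_me=False, struct_as_record=False)
    top = [k for k in mat if not k.startswith("__")]
    if len(top) != 1:
        fail("expected exactly one data variable, found: %s" % ", ".join(top))
    root = mat[top[0]]
    while isinstance(root, np.ndarray) and root.size == 1:
        root = root.ravel()[0]
    names = getattr(root, "_fieldnames", None)
    if not names:
        fail("variable '%s' is not a struct of participants" % top[0])

    rt_rows, toj_rows = [], []
    for pid, name in enumerate(names, start=1):
        sub = getattr(root, name)
        while isinstance(sub, np.ndarray) and sub.size == 1:
            sub = sub.ravel()[0]
        rt_arr = toj_arr = None
        for f in getattr(sub, "_fieldnames", []):
            val = getattr(sub, f)
            if isinstance(val, np.ndarray):
                if val.dtype == object or val.shape[0] == 26:
                    if val.shape[0] != 26:
                        fail("field '%s.%s': RT array has shape %s, expected "
                             "26 rows" % (name, f, val.shape))
                    rt_arr = val
                elif val.shape == (23, 3):
                    toj_arr = np.asarray(val, dtype=float)
                elif val.ndim == 2 and val.shape[1] == 3:
                    fail("field '%s.%s': TOJ array has shape %s, expected "
                         "(23, 3)" % (name, f, val.shape))
        if rt_arr is None:
            fail("participant struct '%s': no 26-row RT cell array found" % name)
        if toj_arr is None:
            fail("participant struct '%s': no 23x3 TOJ array found" % name)
        for ci, (cond, soa) in enumerate(CONDITIONS):
            for lat in cell_latencies(rt_arr[ci]):
                tok = "inf" if math.isinf(lat) else repr(float(lat))
                rt_rows.append([pid, cond, soa, tok])
        for soa, c, n in toj_arr:
            toj_rows.append([pid, int(soa), int(c), int(n)])

    with open(out_dir + "/rt.csv", "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["participant", "condition", "soa", "latency"])
        w.writerows(rt_rows)
    with open(out_dir + "/toj.csv", "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["participant", "soa", "visual_first", "n"])
        w.writerows(toj_rows)


if __name__ == "__main__":
    if len(sys.argv) != 3:
        fail("usage: mat_to_native.py <input.mat> <output_dir>")
    main(sys.argv[1], sys.argv[2])
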