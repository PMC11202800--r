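#!/usr/bin/env python
"""Independent empirical-mode-decomposition reference.

Reads JSON {"signals": [[...], ...], "max_imfs": k} on stdin and writes
JSON {"n_imfs": [...], "first_imf": [[...], ...]} on stdout. Built on
numpy/scipy only; used as a cross-check oracle by the R test suite.
"""
import json
import sys

import numpy as np
from scipy.interpolate import CubicSpline


def local_extrema(x):
    """Strict interior extrema (no plateau handling: oracle inputs are
    continuous random signals where ties have probability zero)."""
    d = np.diff(x)
    maxima = [i for i in range(1, len(x) - 1) if d[i - 1] > 0 and d[i] < 0]
    minima = [i for i in range(1, len(x) - 1) if d[i - 1] < 0 and d[i] > 0]
    return np.array(maxima, dtype=int), np.array(minima, dtype=int)


def zero_crossings(x):
    s = np.sign(x)
    s = s[s != 0]
    return int(np.sum(s[1:] != s[:-1]))


def envelope(idx, val, n):
    k = min(2, len(idx))
    left_i = -idx[:k][::-1]
    right_i = 2 * (n - 1) - idx[-k:][::-1]
    xs = np.concatenate([left_i, idx, right_i])
    ys = np.concatenate([val[:k][::-1], val, val[-k:][::-1]])
    keep = np.concatenate([[True], np.diff(xs) > 0])
    return CubicSpline(xs[keep], ys[keep])(np.arange(n))


def sift_once(h):
    mx, mn = local_extrema(h)
    if len(mx) < 1 or len(mn) < 1:
        return None
    up = envelope(mx, h[mx], len(h))
    lo = envelope(mn, h[mn], len(h))
    return h - (up + lo) / 2.0


def count_ok(h):
    mx, mn = local_extrema(h)
    return abs(len(mx) + len(mn) - zero_crossings(h)) <= 1


def emd(x, max_imfs=3, sd_threshold=0.2, max_iter=10):
    imfs = []
    residual = x.astype(float).copy()
    for _ in range(max_imfs):
        mx, mn = local_extrema(residual)
        if len(mx) + len(mn) < 2:
            break
        h = residual.copy()
        ok = False
        for it in range(3 * max_iter):
            h_new = sift_once(h)
            if h_new is None:
                break
            denom = float(np.sum(h ** 2))
            sd = float(np.sum((h - h_new) ** 2)) / denom if denom > 0 else 0.0
            h = h_new
            if (sd < sd_threshold or it + 1 >= max_iter) and count_ok(h):
                ok = True
                break
        if not ok:
            break
        imfs.append(h)
        residual = residual - h
    return imfs


def main():
    req = json.load(sys.stdin)
    out = {"n_imfs": [], "first_imf": []}
    for sig in req["signals"]:
        imfs = emd(np.asarray(sig, dtype=float),
                   max_imfs=req.get("max_imfs", 3),
                   sd_threshold=req.get("sd_threshold", 0.2),
                   max_iter=req.get("max_iter", 10))
        out["n_imfs"].append(len(imfs))
        out["first_imf"].append(list(imfs[0]) if imfs else [])
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
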