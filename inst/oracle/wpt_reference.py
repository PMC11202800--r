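#!/usr/bin/env python
"""db1 wavelet-packet reference via PyWavelets.

Reads JSON {"signals": [[...], ...], "level": 3} on stdin, writes
{"leaves": [[[...], ...], ...]} with leaves in natural (filter-bank) order.
"""
import json
import sys

import pywt


def main():
    req = json.load(sys.stdin)
    level = req.get("level", 3)
    out = []
    for sig in req["signals"]:
        wp = pywt.WaveletPacket(data=sig, wavelet="db1", mode="zero",
                                maxlevel=level)
        nodes = wp.get_level(level, order="natural")
        out.append([list(map(float, n.data)) for n in nodes])
    json.dump({"leaves": out}, sys.stdout)


if __name__ == "__main__":
    main()
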