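#!/usr/bin/env python
"""Minimal SNIRF (HDF5) bridge.

Converts between a SNIRF container and the package's long-format
tab-separated text files so the R side never needs an HDF5 binding.

Usage:
  snirf_io.py import <series.tsv> <events.tsv> <out.snirf>
  snirf_io.py export <in.snirf> <series.tsv> <events.tsv>

Series TSV: comment header lines '# fs_hz <v>' / '# unit <s>', then columns
time_s, channel, chromophore(HbO|HbR), value. Events TSV: onset_s, hand,
condition.

SNIRF layout written: /formatVersion, /nirs/data1/dataTimeSeries (T x M),
/nirs/data1/time (T), per-column measurementList<k> groups with
sourceIndex = detectorIndex = channel id, dataType = 99999 and
dataTypeLabel = 'HbO'/'HbR', and one /nirs/stim<j> group per
(hand, condition) with name 'hand:condition' and data rows
[onset, duration(=15), value(=1)].
"""
import sys

import h5py
import numpy as np


def read_tsv(path):
    fs = None
    unit = "uM"
    rows = []
    with open(path) as fh:
        header = None
        for line in fh:
            line = line.rstrip("\n")
            if line.startswith("#"):
                parts = line[1:].split()
                if parts and parts[0] == "fs_hz":
                    fs = float(parts[1])
                elif parts and parts[0] == "unit":
                    unit = parts[1]
                continue
            if header is None:
                header = line.split("\t")
                continue
            rows.append(line.split("\t"))
    cols = {name: [r[i] for r in rows] for i, name in enumerate(header)}
    return fs, unit, cols


def cmd_import(series, events, out):
    fs, unit, cols = read_tsv(series)
    t = np.array([float(v) for v in cols["time_s"]])
    ch = np.array([int(v) for v in cols["channel"]])
    chrom = np.array(cols["chromophore"])
    val = np.array([float(v) for v in cols["value"]])
    tgrid = np.unique(t)
    if fs is None:
        fs = (len(tgrid) - 1) / (tgrid[-1] - tgrid[0])
    channels = np.unique(ch)
    meas = [(c, lab) for lab in ("HbO", "HbR") for c in channels]
    data = np.empty((len(tgrid), len(meas)))
    for k, (c, lab) in enumerate(meas):
        sel = (ch == c) & (chrom == lab)
        if sel.sum() != len(tgrid):
            raise SystemExit(f"channel {c}/{lab} missing samples")
        data[:, k] = val[sel][np.argsort(t[sel])]

    with h5py.File(out, "w") as f:
        f.create_dataset("formatVersion", data="1.0")
        nirs = f.create_group("nirs")
        d1 = nirs.create_group("data1")
        d1.create_dataset("dataTimeSeries", data=data)
        d1.create_dataset("time", data=tgrid)
        for k, (c, lab) in enumerate(meas, start=1):
            ml = d1.create_group(f"measurementList{k}")
            ml.create_dataset("sourceIndex", data=int(c))
            ml.create_dataset("detectorIndex", data=int(c))
            ml.create_dataset("wavelengthIndex", data=1)
            ml.create_dataset("dataType", data=99999)
            ml.create_dataset("dataTypeLabel", data=lab)
        meta = nirs.create_group("metaDataTags")
        meta.create_dataset("LengthUnit", data="cm")
        meta.create_dataset("TimeUnit", data="s")
        meta.create_dataset("FrequencyUnit", data="Hz")
        meta.create_dataset("ConcentrationUnit", data=unit)
        groups = {}
        with open(events) as fh:
            header = fh.readline().rstrip("\n").split("\t")
            idx = {name: i for i, name in enumerate(header)}
            for line in fh:
                p = line.rstrip("\n").split("\t")
                key = f"{p[idx['hand']]}:{p[idx['condition']]}"
                groups.setdefault(key, []).append(float(p[idx["onset_s"]]))
        for j, (key, onsets) in enumerate(sorted(groups.items()), start=1):
            st = nirs.create_group(f"stim{j}")
            st.create_dataset("name", data=key)
            st.create_dataset(
                "data",
                data=np.array([[o, 15.0, 1.0] for o in sorted(onsets)]))


def as_str(x):
    v = x[()]
    if isinstance(v, bytes):
        return v.decode()
    if isinstance(v, np.ndarray):
        v = v.item()
        if isinstance(v, bytes):
            return v.decode()
    return str(v)


def cmd_export(path, series, events):
    with h5py.File(path, "r") as f:
        if "nirs" not in f:
            raise SystemExit("not a SNIRF file: missing /nirs")
        nirs = f["nirs"]
        if "data1" not in nirs:
            raise SystemExit("malformed SNIRF: missing /nirs/data1")
        d1 = nirs["data1"]
        data = np.asarray(d1["dataTimeSeries"])
        t = np.asarray(d1["time"]).ravel()
        if len(t) == 2 and data.shape[0] > 2:   # start/step convention
            t = t[0] + t[1] * np.arange(data.shape[0])
        mls = sorted((k for k in d1 if k.startswith("measurementList")),
                     key=lambda k: int(k[len("measurementList"):]))
        if len(mls) != data.shape[1]:
            raise SystemExit("malformed SNIRF: measurementList count != "
                             "data columns under /nirs/data1")
        fs = (len(t) - 1) / (t[-1] - t[0])
        unit = "uM"
        if "metaDataTags" in nirs and "ConcentrationUnit" in nirs["metaDataTags"]:
            unit = as_str(nirs["metaDataTags"]["ConcentrationUnit"])
        with open(series, "w") as out:
            out.write(f"# fs_hz {fs:.10g}\n# unit {unit}\n")
            out.write("time_s\tchannel\tchromophore\tvalue\n")
            for k, name in enumerate(mls):
                ml = d1[name]
                chan = int(np.asarray(ml["sourceIndex"]))
                lab = as_str(ml["dataTypeLabel"])
                if lab not in ("HbO", "HbR"):
                    raise SystemExit(
                        f"unsupported dataTypeLabel '{lab}' in /nirs/data1/{name}")
                for ti, v in zip(t, data[:, k]):
                    out.write(f"{ti:.12g}\t{chan}\t{lab}\t{v:.17g}\n")
        with open(events, "w") as out:
            out.write("onset_s\thand\tcondition\n")
            rows = []
            for k in sorted(k for k in nirs if k.startswith("stim")):
                st = nirs[k]
                name = as_str(st["name"])
                if ":" not in name:
                    continue
                hand, condition = name.split(":", 1)
                arr = np.atleast_2d(np.asarray(st["data"]))
                for row in arr:
                    rows.append((float(row[0]), hand, condition))
            for onset, hand, condition in sorted(rows):
                out.write(f"{onset:.12g}\t{hand}\t{condition}\n")


def main(argv):
    if len(argv) != 5 or argv[1] not in ("import", "export"):
        sys.exit(__doc__)
    if argv[1] == "import":
        cmd_import(argv[2], argv[3], argv[4])
    else:
        cmd_export(argv[2], argv[3], argv[4])


if __name__ == "__main__":
    main(sys.argv)
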