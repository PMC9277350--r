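"""Convert between text GCT (1.2) and HDF5-backed GCTX.

Layout follows the cmap GCTX convention:
  /0/DATA/0/matrix  float32, shape (n_cols, n_rows)  (column-major blocks)
  /0/META/ROW/id    gene identifiers
  /0/META/COL/id    column identifiers

Usage:
  python gctx_convert.py to-gctx in.gct out.gctx
  python gctx_convert.py to-gct  in.gctx out.gct
"""
import sys

import h5py
import numpy as np


def read_gct(path):
    with open(path) as fh:
        ver = fh.readline().strip()
        if not ver.startswith("#1."):
            raise ValueError("not a GCT file: " + path)
        dims = fh.readline().split("\t")
        nr, nc = int(dims[0]), int(dims[1])
        header = fh.readline().rstrip("\n").split("\t")
        col_ids = header[2:2 + nc]
        row_ids, rows = [], []
        for line in fh:
            parts = line.rstrip("\n").split("\t")
            if len(parts) < 2 + nc:
                continue
            row_ids.append(parts[0])
            rows.append([float(v) for v in parts[2:2 + nc]])
    mat = np.asarray(rows, dtype=np.float64)
    if mat.shape != (nr, nc):
        raise ValueError("GCT dimension mismatch in " + path)
    return row_ids, col_ids, mat


def to_gctx(src, dst):
    row_ids, col_ids, mat = read_gct(src)
    with h5py.File(dst, "w") as h5:
        h5.create_dataset("0/DATA/0/matrix", data=mat.T.astype(np.float64))
        str_t = h5py.string_dtype("utf-8")
        h5.create_dataset("0/META/ROW/id", data=np.array(row_ids, dtype=object), dtype=str_t)
        h5.create_dataset("0/META/COL/id", data=np.array(col_ids, dtype=object), dtype=str_t)


def to_gct(src, dst):
    with h5py.File(src, "r") as h5:
        mat = np.asarray(h5["0/DATA/0/matrix"]).T
        row_ids = [r.decode() if isinstance(r, bytes) else str(r) for r in h5["0/META/ROW/id"][...]]
        col_ids = [c.decode() if isinstance(c, bytes) else str(c) for c in h5["0/META/COL/id"][...]]
    with open(dst, "w") as fh:
        fh.write("#1.2\n%d\t%d\n" % (mat.shape[0], mat.shape[1]))
        fh.write("NAME\tDescription\t" + "\t".join(col_ids) + "\n")
        for rid, row in zip(row_ids, mat):
            fh.write(rid + "\t" + rid + "\t" + "\t".join(repr(float(v)) for v in row) + "\n")


def main():
    if len(sys.argv) != 4 or sys.argv[1] not in ("to-gctx", "to-gct"):
        sys.exit(__doc__)
    if sys.argv[1] == "to-gctx":
        to_gctx(sys.argv[2], sys.argv[3])
    else:
        to_gct(sys.argv[2], sys.argv[3])


if __name__ == "__main__":
    main()
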