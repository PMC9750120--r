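"""Minimal cooler-schema HDF5 reader/writer.

Writes the single-resolution cooler layout (chroms/bins/pixels/indexes with
upper-triangular sparse pixels) readable by standard cooler tooling, and
dumps an existing file back to TSV tables. Invoked from R via system2; the
R package has no HDF5 bindings of its own.

Usage:
  python cooler_io.py write OUT.cool BINS.tsv PIXELS.tsv CHROM CHROM_LEN_BP BIN_BP
  python cooler_io.py read  IN.cool  BINS_OUT.tsv PIXELS_OUT.tsv
"""
import sys

import h5py
import numpy as np


def write_cool(path, bins_tsv, pixels_tsv, chrom, chrom_len, bin_bp):
    bins = np.loadtxt(bins_tsv, dtype=np.int64, ndmin=2)       # start, end (bp)
    pixels = np.loadtxt(pixels_tsv, dtype=np.float64, ndmin=2) # bin1, bin2, count
    if pixels.size == 0:
        pixels = np.zeros((0, 3))
    n_bins = bins.shape[0]
    bin1 = pixels[:, 0].astype(np.int64)
    bin2 = pixels[:, 1].astype(np.int64)
    count = pixels[:, 2]
    order = np.lexsort((bin2, bin1))
    bin1, bin2, count = bin1[order], bin2[order], count[order]

    with h5py.File(path, "w") as f:
        f.attrs["format"] = "HDF5::Cooler"
        f.attrs["format-version"] = 3
        f.attrs["bin-type"] = "fixed"
        f.attrs["bin-size"] = int(bin_bp)
        f.attrs["nbins"] = n_bins
        f.attrs["nchroms"] = 1
        f.attrs["nnz"] = len(count)
        f.attrs["storage-mode"] = "symmetric-upper"
        f.attrs["generated-by"] = "polyloopsim"

        g = f.create_group("chroms")
        g.create_dataset("name", data=np.array([chrom], dtype="S32"))
        g.create_dataset("length", data=np.array([chrom_len], dtype=np.int32))

        g = f.create_group("bins")
        g.create_dataset("chrom", data=np.zeros(n_bins, dtype=np.int32))
        g.create_dataset("start", data=bins[:, 0].astype(np.int32))
        g.create_dataset("end", data=bins[:, 1].astype(np.int32))

        g = f.create_group("pixels")
        g.create_dataset("bin1_id", data=bin1)
        g.create_dataset("bin2_id", data=bin2)
        g.create_dataset("count", data=count)

        bin1_offset = np.searchsorted(bin1, np.arange(n_bins + 1), side="left")
        g = f.create_group("indexes")
        g.create_dataset("chrom_offset", data=np.array([0, n_bins], dtype=np.int64))
        g.create_dataset("bin1_offset", data=bin1_offset.astype(np.int64))


def read_cool(path, bins_out, pixels_out):
    with h5py.File(path, "r") as f:
        start = f["bins/start"][:]
        end = f["bins/end"][:]
        name = f["chroms/name"][:][0]
        if isinstance(name, bytes):
            name = name.decode()
        bin1 = f["pixels/bin1_id"][:]
        bin2 = f["pixels/bin2_id"][:]
        count = f["pixels/count"][:]
        bin_size = int(f.attrs.get("bin-size", end[0] - start[0]))
    with open(bins_out, "w") as fh:
        fh.write("# chrom=%s bin_size=%d\n" % (name, bin_size))
        for s, e in zip(start, end):
            fh.write("%d\t%d\n" % (s, e))
    with open(pixels_out, "w") as fh:
        for a, b, c in zip(bin1, bin2, count):
            fh.write("%d\t%d\t%.17g\n" % (a, b, c))


def main(argv):
    cmd = argv[1]
    if cmd == "write":
        write_cool(argv[2], argv[3], argv[4], argv[5], int(argv[6]), int(argv[7]))
    elif cmd == "read":
        read_cool(argv[2], argv[3], argv[4])
    else:
        raise SystemExit("unknown command: %s" % cmd)


if __name__ == "__main__":
    main(sys.argv)
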