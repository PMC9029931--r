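"""Tiny HDF5 shuttle between R and h5py.

Modes:
  write <h5path> <binpath> <N> <H> <W> <layout>
      binpath holds N*H*W uint8 images followed by N*H*W uint8 labels,
      row-major per image (C order: sample, row, col).
      layout "stacked": one (N, H, W, 2) dataset named "dataset";
      layout "named": two datasets "images" and "labels".
  read <h5path> <binpath>
      Auto-detects either layout (any 4-D array with last axis 2, or an
      image/label dataset pair of equal shape), writes "N H W" on stdout and
      the same flat uint8 binary to binpath. Unrecognized layouts exit 3
      after printing every dataset name and shape found.
"""
import sys

import h5py
import numpy as np


def collect(h5):
    out = []
    h5.visititems(lambda name, obj: out.append((name, obj))
                  if isinstance(obj, h5py.Dataset) else None)
    return out


def main():
    mode = sys.argv[1]
    if mode == "write":
        h5path, binpath, n, h, w, layout = sys.argv[2:8]
        n, h, w = int(n), int(h), int(w)
        flat = np.fromfile(binpath, dtype=np.uint8)
        imgs = flat[: n * h * w].reshape(n, h, w)
        labs = flat[n * h * w:].reshape(n, h, w)
        with h5py.File(h5path, "w") as f:
            if layout == "stacked":
                f.create_dataset("dataset", data=np.stack([imgs, labs], axis=-1))
            else:
                f.create_dataset("images", data=imgs)
                f.create_dataset("labels", data=labs)
        return 0
    if mode == "read":
        h5path, binpath = sys.argv[2:4]
        with h5py.File(h5path, "r") as f:
            dsets = collect(f)
            imgs = labs = None
            for name, d in dsets:
                if d.ndim == 4 and d.shape[-1] == 2:
                    arr = d[...]
                    imgs, labs = arr[..., 0], arr[..., 1]
                    break
            if imgs is None and len(dsets) >= 2:
                byname = {name.split("/")[-1].lower(): d for name, d in dsets}
                for a, b in (("images", "labels"), ("image", "label"),
                             ("x", "y"), ("data", "truth")):
                    if a in byname and b in byname and byname[a].shape == byname[b].shape:
                        imgs, labs = byname[a][...], byname[b][...]
                        break
            if imgs is None:
                print("unrecognized HDF5 layout; datasets found:", file=sys.stderr)
                for name, d in dsets:
                    print(f"  {name}: shape {d.shape} dtype {d.dtype}", file=sys.stderr)
                return 3
        imgs = np.asarray(imgs)
        labs = np.asarray(labs)
        if imgs.ndim == 2:
            imgs = imgs[None]
            labs = labs[None]
        n, h, w = imgs.shape
        np.concatenate([
            np.rint(imgs).astype(np.int64).clip(0, 255).astype(np.uint8).ravel(),
            np.rint(labs).astype(np.int64).clip(0, 255).astype(np.uint8).ravel(),
        ]).tofile(binpath)
        print(n, h, w)
        return 0
    print("unknown mode", file=sys.stderr)
    return 2


if __name__ == "__main__":
    sys.exit(main())
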