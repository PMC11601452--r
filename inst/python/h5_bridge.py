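"""Small h5py shim used for HDF5/NWB I/O.

Subcommands
  read_lfp  <in.h5> <prefix>   -> writes <prefix>_traces.csv, <prefix>_meta.csv
  write_lfp <out.h5> <prefix>  <- reads the same pair of CSVs
  read_nwb  <in.nwb> <prefix>  -> writes <prefix>_spikes.csv and, when an
                                  ElectricalSeries exists, the LFP CSV pair.

The NWB reader walks the plain HDF5 layout (units/spike_times with its index,
the electrode table under general/extracellular_ephys, acquisition/*
ElectricalSeries); it does not require pynwb.
"""
import sys

import numpy as np
import h5py


def read_lfp(path, prefix):
    with h5py.File(path, "r") as f:
        traces = np.asarray(f["traces"])
        pos = np.asarray(f["positions"])
        sr = float(np.asarray(f["sample_rate"]).ravel()[0])
        if "electrode_ids" in f:
            ids = [x.decode() if isinstance(x, bytes) else str(x)
                   for x in np.asarray(f["electrode_ids"]).ravel()]
        else:
            ids = [f"e{i+1}" for i in range(traces.shape[0])]
    np.savetxt(prefix + "_traces.csv", traces, delimiter=",", fmt="%.10g")
    with open(prefix + "_meta.csv", "w") as fh:
        fh.write("electrode_id,x_um,y_um,sample_rate\n")
        for i, eid in enumerate(ids):
            fh.write(f"{eid},{pos[i,0]:.10g},{pos[i,1]:.10g},{sr:.10g}\n")


def write_lfp(path, prefix):
    traces = np.loadtxt(prefix + "_traces.csv", delimiter=",", ndmin=2)
    ids, xs, ys, srs = [], [], [], []
    with open(prefix + "_meta.csv") as fh:
        next(fh)
        for line in fh:
            eid, x, y, sr = line.strip().split(",")
            ids.append(eid)
            xs.append(float(x))
            ys.append(float(y))
            srs.append(float(sr))
    with h5py.File(path, "w") as f:
        f.create_dataset("traces", data=traces)
        f.create_dataset("positions", data=np.column_stack([xs, ys]))
        f.create_dataset("sample_rate", data=srs[0])
        f.create_dataset("electrode_ids",
                         data=np.array(ids, dtype=h5py.string_dtype()))


def _find_electrical_series(f):
    acq = f.get("acquisition")
    if acq is None:
        return None
    for name in acq:
        grp = acq[name]
        if isinstance(grp, h5py.Group) and "data" in grp:
            return grp
    return None


def read_nwb(path, prefix):
    with h5py.File(path, "r") as f:
        wrote_any = False
        if "units" in f and "units/spike_times" in f:
            st = np.asarray(f["units/spike_times"]).ravel()
            idx = np.asarray(f["units/spike_times_index"]).ravel().astype(int)
            if "units/id" in f:
                raw_ids = np.asarray(f["units/id"]).ravel()
                uids = [x.decode() if isinstance(x, bytes) else str(x)
                        for x in raw_ids]
            else:
                uids = [str(i) for i in range(len(idx))]
            ux = (np.asarray(f["units/x_um"]).ravel()
                  if "units/x_um" in f else np.zeros(len(idx)))
            uy = (np.asarray(f["units/y_um"]).ravel()
                  if "units/y_um" in f else np.zeros(len(idx)))
            with open(prefix + "_spikes.csv", "w") as fh:
                fh.write("unit_id,time_s,x_um,y_um\n")
                start = 0
                for u, stop in enumerate(idx):
                    for t in st[start:stop]:
                        fh.write(f"{uids[u]},{t:.10g},{ux[u]:.10g},{uy[u]:.10g}\n")
                    start = stop
            wrote_any = True
        es = _find_electrical_series(f)
        if es is not None:
            data = np.asarray(es["data"])
            if data.ndim == 1:
                data = data[None, :]
            elif data.shape[0] > data.shape[1]:
                data = data.T  # NWB stores time x channels
            sr = float(np.asarray(es["starting_time"].attrs.get("rate", 0.0))
                       ) if "starting_time" in es else 0.0
            if sr <= 0 and "rate" in es.attrs:
                sr = float(es.attrs["rate"])
            n = data.shape[0]
            etab = f.get("general/extracellular_ephys/electrodes")
            if etab is not None and "x" in etab:
                xs = np.asarray(etab["x"]).ravel()[:n]
                ys = np.asarray(etab["y"]).ravel()[:n]
            else:
                xs = np.zeros(n)
                ys = np.zeros(n)
            np.savetxt(prefix + "_traces.csv", data, delimiter=",", fmt="%.10g")
            with open(prefix + "_meta.csv", "w") as fh:
                fh.write("electrode_id,x_um,y_um,sample_rate\n")
                for i in range(n):
                    fh.write(f"e{i+1},{xs[i]:.10g},{ys[i]:.10g},{sr:.10g}\n")
            wrote_any = True
        if not wrote_any:
            sys.exit("no units table or ElectricalSeries found")


def main():
    cmd = sys.argv[1]
    if cmd == "read_lfp":
        read_lfp(sys.argv[2], sys.argv[3])
    elif cmd == "write_lfp":
        write_lfp(sys.argv[2], sys.argv[3])
    elif cmd == "read_nwb":
        read_nwb(sys.argv[2], sys.argv[3])
    else:
        sys.exit(f"unknown subcommand {cmd}")


if __name__ == "__main__":
    main()
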