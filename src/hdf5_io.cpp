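// Minimal Taiyaki-style mapped-signal HDF5 reader/writer against the
// libhdf5 C API. Layout: one group per read under /Reads, holding
//   Dacs          float64 raw signal
//   Reference     int32 bases encoded 0..3 (A, C, G, U)
//   Ref_to_signal int32, length = len(Reference) + 1: each base's first
//                 signal sample (0-based) plus the total sample count.
#include <Rcpp.h>
#include <hdf5.h>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Closer {
  hid_t id;
  herr_t (*fn)(hid_t);
  ~Closer() { if (id >= 0) fn(id); }
};

void silence_errors() { H5Eset_auto2(H5E_DEFAULT, NULL, NULL); }

void write_vec(hid_t grp, const char* name, hid_t type, const void* data,
               hsize_t n) {
  hid_t sp = H5Screate_simple(1, &n, NULL);
  Closer csp{sp, H5Sclose};
  hid_t ds = H5Dcreate2(grp, name, type, sp, H5P_DEFAULT, H5P_DEFAULT,
                        H5P_DEFAULT);
  if (ds < 0) stop("failed to create dataset %s", name);
  Closer cds{ds, H5Dclose};
  if (H5Dwrite(ds, type, H5S_ALL, H5S_ALL, H5P_DEFAULT, data) < 0)
    stop("failed to write dataset %s", name);
}

bool read_vec_double(hid_t grp, const char* name, std::vector<double>& out) {
  hid_t ds = H5Dopen2(grp, name, H5P_DEFAULT);
  if (ds < 0) return false;
  Closer cds{ds, H5Dclose};
  hid_t sp = H5Dget_space(ds);
  Closer csp{sp, H5Sclose};
  hssize_t n = H5Sget_simple_extent_npoints(sp);
  if (n < 0) return false;
  out.resize((size_t)n);
  return H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                 out.data()) >= 0;
}

bool read_vec_int(hid_t grp, const char* name, std::vector<int>& out) {
  hid_t ds = H5Dopen2(grp, name, H5P_DEFAULT);
  if (ds < 0) return false;
  Closer cds{ds, H5Dclose};
  hid_t sp = H5Dget_space(ds);
  Closer csp{sp, H5Sclose};
  hssize_t n = H5Sget_simple_extent_npoints(sp);
  if (n < 0) return false;
  out.resize((size_t)n);
  return H5Dread(ds, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                 out.data()) >= 0;
}

}  // namespace

// [[Rcpp::export]]
void h5_write_mapped(std::string path, CharacterVector ids, List signals,
                     List refs, List maps) {
  silence_errors();
  hid_t f = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (f < 0) stop("cannot create HDF5 file: " + path);
  Closer cf{f, H5Fclose};
  // file-level alphabet attribute
  {
    hid_t sp = H5Screate(H5S_SCALAR);
    Closer csp{sp, H5Sclose};
    hid_t ty = H5Tcopy(H5T_C_S1);
    Closer cty{ty, H5Tclose};
    H5Tset_size(ty, 4);
    hid_t at = H5Acreate2(f, "alphabet", ty, sp, H5P_DEFAULT, H5P_DEFAULT);
    Closer cat{at, H5Aclose};
    H5Awrite(at, ty, "ACGU");
  }
  hid_t reads = H5Gcreate2(f, "Reads", H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
  if (reads < 0) stop("failed to create /Reads group");
  Closer cr{reads, H5Gclose};
  for (R_xlen_t i = 0; i < ids.size(); ++i) {
    std::string id = as<std::string>(ids[i]);
    hid_t g = H5Gcreate2(reads, id.c_str(), H5P_DEFAULT, H5P_DEFAULT,
                         H5P_DEFAULT);
    if (g < 0) stop("failed to create read group " + id);
    Closer cg{g, H5Gclose};
    NumericVector s = signals[i];
    IntegerVector r = refs[i];
    IntegerVector m = maps[i];
    write_vec(g, "Dacs", H5T_NATIVE_DOUBLE, REAL(s), (hsize_t)s.size());
    write_vec(g, "Reference", H5T_NATIVE_INT, INTEGER(r), (hsize_t)r.size());
    write_vec(g, "Ref_to_signal", H5T_NATIVE_INT, INTEGER(m),
              (hsize_t)m.size());
  }
}

// [[Rcpp::export]]
CharacterVector h5_list_reads(std::string path) {
  silence_errors();
  hid_t f = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (f < 0) stop("cannot open HDF5 file: " + path);
  Closer cf{f, H5Fclose};
  hid_t g = H5Gopen2(f, "Reads", H5P_DEFAULT);
  if (g < 0) stop("no /Reads group in " + path);
  Closer cg{g, H5Gclose};
  H5G_info_t info;
  if (H5Gget_info(g, &info) < 0) stop("cannot query /Reads group");
  CharacterVector out((R_xlen_t)info.nlinks);
  for (hsize_t i = 0; i < info.nlinks; ++i) {
    ssize_t len = H5Lget_name_by_idx(g, ".", H5_INDEX_NAME, H5_ITER_INC, i,
                                     NULL, 0, H5P_DEFAULT);
    std::vector<char> buf((size_t)len + 1);
    H5Lget_name_by_idx(g, ".", H5_INDEX_NAME, H5_ITER_INC, i, buf.data(),
                       buf.size(), H5P_DEFAULT);
    out[(R_xlen_t)i] = std::string(buf.data());
  }
  return out;
}

// Reads the requested read groups one at a time; a malformed group yields
// R NULL in its slot so the caller can skip it with a warning.
// [[Rcpp::export]]
List h5_read_reads(std::string path, CharacterVector ids) {
  silence_errors();
  hid_t f = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (f < 0) stop("cannot open HDF5 file: " + path);
  Closer cf{f, H5Fclose};
  List out(ids.size());
  out.names() = ids;
  for (R_xlen_t i = 0; i < ids.size(); ++i) {
    std::string gpath = "Reads/" + as<std::string>(ids[i]);
    hid_t g = H5Gopen2(f, gpath.c_str(), H5P_DEFAULT);
    if (g < 0) { out[i] = R_NilValue; continue; }
    Closer cg{g, H5Gclose};
    std::vector<double> sig;
    std::vector<int> ref, map;
    if (!read_vec_double(g, "Dacs", sig) || !read_vec_int(g, "Reference", ref) ||
        !read_vec_int(g, "Ref_to_signal", map) || sig.empty() ||
        map.size() != ref.size() + 1) {
      out[i] = R_NilValue;
      continue;
    }
    out[i] = List::create(_["signal"] = NumericVector(sig.begin(), sig.end()),
                          _["reference"] = IntegerVector(ref.begin(), ref.end()),
                          _["ref_to_signal"] = IntegerVector(map.begin(), map.end()));
  }
  return out;
}
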