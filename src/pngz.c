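/* zlib bindings for PNG chunk assembly: compress/uncompress (RFC 1950
 * streams, as required inside IDAT) and CRC-32 for chunk checksums. */

#include <R.h>
#include <Rinternals.h>
#include <zlib.h>

SEXP c_zlib_compress(SEXP raw_, SEXP level_)
{
    uLong srclen = (uLong) XLENGTH(raw_);
    uLong bound = compressBound(srclen);
    SEXP buf = PROTECT(allocVector(RAWSXP, bound));
    uLongf destlen = bound;
    int level = asInteger(level_);
    int rc = compress2(RAW(buf), &destlen, RAW(raw_), srclen, level);
    if (rc != Z_OK)
        error("zlib compress2 failed (rc=%d)", rc);
    SEXP out = PROTECT(allocVector(RAWSXP, destlen));
    memcpy(RAW(out), RAW(buf), destlen);
    UNPROTECT(2);
    return out;
}

SEXP c_zlib_uncompress(SEXP raw_, SEXP size_)
{
    uLongf destlen = (uLongf) asReal(size_);
    SEXP out = PROTECT(allocVector(RAWSXP, destlen));
    int rc = uncompress(RAW(out), &destlen, RAW(raw_), (uLong) XLENGTH(raw_));
    if (rc != Z_OK)
        error("zlib uncompress failed (rc=%d)", rc);
    if (destlen != (uLongf) XLENGTH(out)) {
        SEXP trimmed = PROTECT(allocVector(RAWSXP, destlen));
        memcpy(RAW(trimmed), RAW(out), destlen);
        UNPROTECT(2);
        return trimmed;
    }
    UNPROTECT(1);
    return out;
}

SEXP c_crc32(SEXP raw_)
{
    uLong crc = crc32(0L, Z_NULL, 0);
    crc = crc32(crc, RAW(raw_), (uInt) XLENGTH(raw_));
    return ScalarReal((double) crc);
}

static const R_CallMethodDef CallEntries[] = {
    {"c_zlib_compress",   (DL_FUNC) &c_zlib_compress,   2},
    {"c_zlib_uncompress", (DL_FUNC) &c_zlib_uncompress, 2},
    {"c_crc32",           (DL_FUNC) &c_crc32,           1},
    {NULL, NULL, 0}
};

void R_init_ocsr(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
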