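a
an
the
and
or
but
nor
so
yet
although
because
since
unless
until
while
whereas
whether
though
if
than
that
when
whenever
where
wherever
once
as
about
above
across
after
against
along
among
around
at
before
behind
below
beneath
beside
between
beyond
by
down
during
except
for
from
in
inside
into
near
of
off
on
onto
out
outside
over
past
through
to
toward
towards
under
up
upon
via
with
within
without
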