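a
about
above
after
again
against
all
am
an
and
any
are
as
at
be
because
been
before
being
below
between
both
but
by
continue
could
denied
denies
describes
did
do
does
doing
down
during
each
feels
few
for
from
further
had
has
have
having
he
her
here
hers
herself
him
himself
his
how
i
if
in
into
is
it
its
itself
just
me
more
most
my
myself
no
nor
not
noted
notes
now
of
off
on
once
only
or
other
our
ours
ourselves
out
over
own
plan
reported
reports
same
she
should
since
so
some
started
states
such
than
that
the
their
theirs
them
themselves
then
there
these
they
this
those
through
to
today
too
under
until
up
very
was
we
were
what
when
where
which
while
who
whom
why
will
with
would
you
your
yours
yourself
yourselves
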